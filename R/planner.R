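# Planner: the protocol's quantitative bench arithmetic — DNA molarity
# conversion, serial dilutions, sequencing depth / multiplexing capacity, and
# the loading-mix composition.

#' Convert a DNA mass concentration to molarity
#'
#' `[nM] = ([ng/uL] / (length_bp * 660)) * 1e6`, using the conventional
#' 660 g mol^-1 bp^-1 average mass of double-stranded DNA (no GC-content
#' correction).
#'
#' @param mass_conc mass concentration in ng/uL.
#' @param length_bp amplicon length in base pairs.
#' @return molar concentration in nM.
#' @export
mass_to_molar <- function(mass_conc, length_bp) {
  if (any(mass_conc <= 0) || any(length_bp <= 0))
    stop("mass concentration and length must be positive")
  (mass_conc / (length_bp * 660)) * 1e6
}

#' Inverse of [mass_to_molar()]
#'
#' @param molar_conc molar concentration in nM.
#' @param length_bp amplicon length in base pairs.
#' @return mass concentration in ng/uL.
#' @export
molar_to_mass <- function(molar_conc, length_bp) {
  if (any(molar_conc <= 0) || any(length_bp <= 0))
    stop("molar concentration and length must be positive")
  molar_conc * length_bp * 660 / 1e6
}

#' Concentration after a serial dilution
#'
#' Each step carries `carried` volume of the current solution and adds
#' `added` volume of diluent, multiplying the concentration by
#' `carried / (carried + added)`.
#'
#' @param initial_conc starting concentration (any unit).
#' @param steps a list of steps, each a numeric vector or list with elements
#'   `added` and `carried` (volumes in the same unit, e.g. uL).
#' @return the final concentration, in the unit of `initial_conc`.
#' @examples
#' # 2 uL of a 10 nM pool + 3 uL water -> 4 nM
#' dilution_series(10, list(c(added = 3, carried = 2)))
#' # 5 uL of 4 nM + 5 uL NaOH, then + 990 uL buffer -> 0.02 nM = 20 pM
#' dilution_series(4, list(c(added = 5, carried = 5),
#'                         c(added = 990, carried = 10)))
#' @export
dilution_series <- function(initial_conc, steps) {
  conc <- initial_conc
  for (s in steps) {
    s <- as.list(s)
    added <- s$added; carried <- s$carried
    if (is.null(added) || is.null(carried) || carried <= 0 || added < 0)
      stop("each step needs carried > 0 and added >= 0")
    if (carried + added <= 0) stop("zero total volume")
    conc <- conc * carried / (carried + added)
  }
  conc
}

#' Sequencing depth and multiplexing plan
#'
#' How many reads one sample needs (`library_size * reads_per_variant`) and
#' how many samples a kit can multiplex (floor of kit yield over per-sample
#' reads). For a 10,000-sequence library at the conventional 200
#' reads/sequence one sample needs 2 million reads, so a 20-30 million read
#' kit carries 10-15 samples.
#'
#' @param library_size number of distinct sequences in the library.
#' @param reads_per_variant target unsorted reads per sequence (200-500 is
#'   the working range).
#' @param kit_yield total reads the kit produces.
#' @return a `depth_plan`: list with the inputs plus `per_sample_reads` and
#'   `max_samples`.
#' @export
depth_plan <- function(library_size, reads_per_variant, kit_yield) {
  stopifnot(library_size >= 1, reads_per_variant >= 1, kit_yield >= 1)
  per_sample <- library_size * reads_per_variant
  structure(list(library_size = library_size,
                 reads_per_variant = reads_per_variant,
                 kit_yield = kit_yield,
                 per_sample_reads = per_sample,
                 max_samples = floor(kit_yield / per_sample)),
            class = "depth_plan")
}

#' @export
print.depth_plan <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",", scientific = FALSE)
  cat("<depth_plan>", fmt(x$library_size), "sequences x",
      x$reads_per_variant, "reads =", fmt(x$per_sample_reads),
      "reads/sample; kit", fmt(x$kit_yield), "->", x$max_samples,
      "samples\n")
  invisible(x)
}

#' Loading-mix composition for a sequencing run
#'
#' Volumes of pooled sample, spike-in (PhiX) and diluent that give a final
#' mix of the target total molarity and volume with the requested molar
#' spike share (e.g. 600 uL at 8-12 pM with 5% PhiX).
#'
#' @param target_conc target total DNA concentration (e.g. pM).
#' @param target_volume final volume (e.g. uL).
#' @param spike_fraction molar fraction of the spike-in, in [0, 1).
#' @param stock_sample,stock_spike stock concentrations, same unit as
#'   `target_conc`.
#' @return list with `sample_volume`, `spike_volume`, `diluent_volume` (they
#'   sum to `target_volume`).
#' @export
loading_mix <- function(target_conc, target_volume, spike_fraction,
                        stock_sample, stock_spike = stock_sample) {
  stopifnot(target_conc > 0, target_volume > 0,
            spike_fraction >= 0, spike_fraction < 1)
  total_amount <- target_conc * target_volume
  v_sample <- (1 - spike_fraction) * total_amount / stock_sample
  v_spike <- if (spike_fraction > 0)
    spike_fraction * total_amount / stock_spike else 0
  v_dil <- target_volume - v_sample - v_spike
  if (v_dil < 0) {
    lim <- if (v_sample > v_spike) "sample" else "spike"
    stop("infeasible target: the ", lim,
         " stock is too dilute for the requested mix")
  }
  list(sample_volume = v_sample, spike_volume = v_spike,
       diluent_volume = v_dil)
}
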
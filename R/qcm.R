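#' Quartz crystal description for Sauerbrey conversion
#'
#' Defaults are a 5 MHz fundamental crystal with mass sensitivity
#' C = 17.7 ng cm^-2 Hz^-1 (referenced to the fundamental), read at the
#' third overtone with raw (un-normalised) frequency shifts. All four
#' constants are explicit arguments, never hard-coded downstream.
#'
#' @param fundamental_frequency Fundamental resonance, Hz.
#' @param sensitivity_constant Mass sensitivity, ng cm^-2 Hz^-1.
#' @param overtone Odd overtone order n (>= 1).
#' @param frequency_is_normalized Whether supplied frequency shifts are
#'   already divided by the overtone order (delta f / n).
#' @return An object of class `crystal_spec`.
#' @export
crystal_spec <- function(fundamental_frequency = 5e6,
                         sensitivity_constant = 17.7,
                         overtone = 3,
                         frequency_is_normalized = FALSE) {
  if (overtone < 1 || overtone %% 2 != 1) {
    stop("`overtone` must be an odd integer >= 1", call. = FALSE)
  }
  stopifnot(sensitivity_constant > 0, fundamental_frequency > 0)
  structure(
    list(fundamental_frequency = fundamental_frequency,
         sensitivity_constant = sensitivity_constant,
         overtone = as.integer(overtone),
         frequency_is_normalized = isTRUE(frequency_is_normalized)),
    class = "crystal_spec"
  )
}

#' Sauerbrey conversion of a frequency drop to areal mass
#'
#' mass = C * delta_f / n for raw overtone frequencies, or C * delta_f if
#' the input is already overtone-normalised. Rigid-film (Sauerbrey)
#' behaviour is assumed; supply `dissipation_ratio` (delta D per Hz of
#' normalised delta f) to get a warning when the film is too soft for the
#' relation to hold.
#'
#' @param delta_f Frequency drop magnitude(s), Hz (>= 0).
#' @param crystal A [crystal_spec()].
#' @param dissipation_ratio Optional |delta D| / (delta f / n) value(s),
#'   1e-6/Hz.
#' @param rigidity_limit Warning threshold for `dissipation_ratio`
#'   (default 0.4e-6 per Hz).
#' @return Areal mass(es), ng/cm^2.
#' @export
#' @examples
#' sauerbrey_mass(33) # 17.7 * 33 / 3
sauerbrey_mass <- function(delta_f, crystal = crystal_spec(),
                           dissipation_ratio = NULL,
                           rigidity_limit = 0.4) {
  stopifnot(inherits(crystal, "crystal_spec"))
  if (any(delta_f < 0)) {
    stop("`delta_f` must be the magnitude of the drop (>= 0)", call. = FALSE)
  }
  if (!is.null(dissipation_ratio) &&
      any(dissipation_ratio > rigidity_limit)) {
    warning("dissipation/frequency ratio exceeds the rigidity limit; ",
            "the Sauerbrey relation underestimates soft-film mass",
            call. = FALSE)
  }
  if (crystal$frequency_is_normalized) {
    crystal$sensitivity_constant * delta_f
  } else {
    crystal$sensitivity_constant * delta_f / crystal$overtone
  }
}

# DNA residue masses (g/mol): 2'-deoxynucleoside-5'-monophosphate minus
# water, i.e. the internal chain residue. Free-acid monophosphates:
# dAMP 331.22, dCMP 307.20, dGMP 347.22, dTMP 322.21 (IUPAC 2021 atomic
# weights); residue = monophosphate - H2O (18.02).
.dna_residue_mass <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
# a 5'-OH, 3'-OH oligo has one phosphate fewer than the residue sum:
# subtract HPO3 (79.98) and add H2O (18.02)
.oligo_end_correction <- -61.96

# terminal modification masses (g/mol), added to the unmodified oligo:
# hexyl linker attached through an additional phosphodiester.
#   amino_c6: -PO(OH)-O-(CH2)6-NH2  (C6H15NO4P - H2O)
#   thiol_c6: -PO(OH)-O-(CH2)6-SH   (C6H15O4PS - H2O)
.end_mod_mass <- c(amino_c6 = 179.2, thiol_c6 = 196.2)

#' Molecular weight of a modified DNA oligonucleotide
#'
#' Sum of per-nucleotide residue masses, the 5'/3'-OH end correction, and
#' the masses of any terminal modifications from the shipped table
#' (`amino_c6`, `thiol_c6`).
#'
#' @param sequence DNA sequence (A/C/G/T only).
#' @param end_mods Character vector of modification names (default the
#'   RD1 pair: 5' amino-C6 and 3' thiol-C6); use `character(0)` for an
#'   unmodified oligo.
#' @return Molecular weight in g/mol.
#' @export
#' @examples
#' sequence_mw(rd1_sequence())
sequence_mw <- function(sequence, end_mods = c("amino_c6", "thiol_c6")) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) == 0) stop("empty sequence", call. = FALSE)
  if (!all(bases %in% names(.dna_residue_mass))) {
    stop("unknown base(s): ",
         paste(unique(setdiff(bases, names(.dna_residue_mass))), collapse = ", "),
         call. = FALSE)
  }
  if (length(end_mods) > 0 && !all(end_mods %in% names(.end_mod_mass))) {
    stop("unknown end modification(s): ",
         paste(setdiff(end_mods, names(.end_mod_mass)), collapse = ", "),
         call. = FALSE)
  }
  sum(.dna_residue_mass[bases]) + .oligo_end_correction +
    sum(.end_mod_mass[end_mods])
}

#' Molecular surface density from areal mass
#'
#' density = mass \[ng/cm^2\] x 1e-9 / MW x N_A, in molecules/cm^2.
#'
#' @param mass Areal mass, ng/cm^2 (> 0).
#' @param mw Molecular weight, g/mol (> 0).
#' @return Surface density, molecules/cm^2.
#' @export
surface_density <- function(mass, mw) {
  if (any(mass < 0) || any(mw <= 0)) {
    stop("`mass` must be >= 0 and `mw` > 0", call. = FALSE)
  }
  mass * 1e-9 / mw * .NA_const
}

#' Ratio of two surface densities as a percentage
#'
#' Used for coupling efficiencies (aptamers per activated -COOH group)
#' and bound fractions (targets per immobilised aptamer).
#'
#' @param numerator,denominator Surface densities (denominator > 0).
#' @return Percentage, 100 * numerator / denominator.
#' @export
#' @examples
#' fraction_percent(5.5e12, 1.1e13) # 50
fraction_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  100 * numerator / denominator
}

#' QCM trace container
#'
#' @param times Ascending time stamps, s.
#' @param delta_f Frequency shift relative to baseline, Hz (signed;
#'   adsorption shows as decreasing values).
#' @param overtone Overtone order of the recorded frequency.
#' @param annotations Tibble of labelled intervals with columns `label`,
#'   `start_s`, `end_s` (e.g. SAM, EDC/NHS, aptamer, wash, endotoxin).
#' @return An object of class `qcm_trace`: tibble `time_s`, `delta_f_hz`
#'   with attributes `overtone`, `annotations`.
#' @export
qcm_trace <- function(times, delta_f, overtone = 3, annotations = NULL) {
  stopifnot(length(times) == length(delta_f))
  if (is.unsorted(times)) stop("`times` must be ascending", call. = FALSE)
  out <- tibble::tibble(time_s = times, delta_f_hz = delta_f)
  attr(out, "overtone") <- overtone
  attr(out, "annotations") <- annotations
  class(out) <- c("qcm_trace", class(out))
  out
}

#' Linear binding slope over a labelled trace interval
#'
#' Ordinary least squares of delta f against time over the annotated
#' interval, reported in Hz/min.
#'
#' @param trace A [qcm_trace()] with annotations.
#' @param interval_label Label of the interval to fit.
#' @return Slope in Hz/min (negative for ongoing adsorption).
#' @export
fit_binding_slope <- function(trace, interval_label) {
  ann <- attr(trace, "annotations")
  if (is.null(ann) || !interval_label %in% ann$label) {
    stop("no annotated interval labelled '", interval_label, "'", call. = FALSE)
  }
  iv <- ann[ann$label == interval_label, ][1, ]
  sel <- trace$time_s >= iv$start_s & trace$time_s <= iv$end_s
  if (sum(sel) < 3) {
    stop("interval '", interval_label, "' holds fewer than 3 points",
         call. = FALSE)
  }
  fit <- stats::lm(delta_f_hz ~ time_s, data = trace[sel, ])
  unname(stats::coef(fit)[2]) * 60
}
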
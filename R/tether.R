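#' Describe one segment of a composite tether
#'
#' A tether is an ordered list of segments, each either a flexible
#' freely-jointed (Kuhn-discretised worm-like) chain or a rigid rod.
#'
#' @param label Segment name.
#' @param contour_length Contour length in nm (> 0).
#' @param kuhn_length Kuhn length in nm (> 0; ignored for rigid segments,
#'   which are sampled as a single inextensible rod of `contour_length`).
#' @param rigid Logical; `TRUE` for a rigid rod.
#' @return A one-row tibble with columns `label`, `contour_length`,
#'   `kuhn_length`, `rigid`.
#' @export
segment_spec <- function(label, contour_length, kuhn_length = contour_length,
                         rigid = FALSE) {
  stopifnot(is.character(label), length(label) == 1)
  if (!is.numeric(contour_length) || length(contour_length) != 1 ||
      !is.finite(contour_length) || contour_length <= 0) {
    stop("`contour_length` must be a single positive number (nm)", call. = FALSE)
  }
  if (!is.numeric(kuhn_length) || length(kuhn_length) != 1 ||
      !is.finite(kuhn_length) || kuhn_length <= 0) {
    stop("`kuhn_length` must be a single positive number (nm)", call. = FALSE)
  }
  tibble::tibble(
    label = label,
    contour_length = contour_length,
    kuhn_length = kuhn_length,
    rigid = isTRUE(rigid)
  )
}

#' Gold nanoparticle description
#'
#' @param diameter Particle diameter in nm (default 80).
#' @param material_label Free-text label.
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(diameter = 80, material_label = "Au") {
  if (!is.numeric(diameter) || length(diameter) != 1 || diameter <= 0) {
    stop("`diameter` must be a single positive number (nm)", call. = FALSE)
  }
  structure(
    list(diameter = diameter, material_label = material_label),
    class = "particle_spec"
  )
}

#' Assemble a tether from explicit segments
#'
#' Low-level constructor for arbitrary composite chains (single rods,
#' custom linker layouts). [build_tether_spec()] is the high-level
#' sequence-driven builder.
#'
#' @param segments A tibble of [segment_spec()] rows (bound together in
#'   order from film to particle).
#' @param state `"unbound"` or `"bound"` (metadata).
#' @param sequence Optional DNA sequence the spec describes.
#' @return A `tether_spec`.
#' @export
tether_spec <- function(segments, state = "unbound", sequence = NA_character_) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1,
            all(c("label", "contour_length", "kuhn_length", "rigid") %in%
                  names(segments)))
  structure(
    list(segments = tibble::as_tibble(segments), state = state,
         endotoxin_length = NA_real_, sequence = sequence,
         total_contour = sum(segments$contour_length)),
    class = "tether_spec"
  )
}

#' Build a composite worm-like-chain description of the aptamer tether
#'
#' The unbound tether is `linker | ssDNA(all nucleotides) | linker`. In the
#' bound state the central binding region collapses into one rigid
#' "complex" segment of length `endotoxin_length`, leaving the two flanking
#' arms as ssDNA: `linker | ssDNA(flank) | complex | ssDNA(flank) | linker`.
#'
#' @param sequence DNA sequence (A/C/G/T), 5' to 3'. Default [rd1_sequence()].
#' @param linker_contour Rigid end-linker length in nm, one at each end.
#' @param ssdna_rise ssDNA contour rise per nucleotide, nm/nt.
#' @param ssdna_kuhn ssDNA Kuhn length, nm.
#' @param state `"unbound"` or `"bound"`.
#' @param endotoxin_length Rigid aptamer-endotoxin complex length in nm;
#'   bound state only, must lie in \[2, 4\] nm (0 is allowed only together
#'   with `binding_region_nt = 0`, the degenerate empty fold).
#' @param binding_region_nt Number of central nucleotides that fold around
#'   the target in the bound state (default 36).
#' @return An object of class `tether_spec`: list with `segments` (tibble of
#'   segment rows), `state`, `endotoxin_length`, `sequence`, and
#'   `total_contour` (nm).
#' @export
#' @examples
#' build_tether_spec(state = "bound", endotoxin_length = 3)
build_tether_spec <- function(sequence = rd1_sequence(),
                              linker_contour = 1.25,
                              ssdna_rise = 0.63,
                              ssdna_kuhn = 3.0,
                              state = c("unbound", "bound"),
                              endotoxin_length = 3,
                              binding_region_nt = 36) {
  state <- match.arg(state)
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    bad <- unique(bases[!bases %in% c("A", "C", "G", "T")])
    stop("unknown base(s) in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_nt <- length(bases)
  stopifnot(ssdna_rise > 0, ssdna_kuhn > 0, linker_contour >= 0)

  linker_rows <- function(lab) {
    if (linker_contour > 0) {
      segment_spec(lab, linker_contour, rigid = TRUE)
    } else {
      NULL
    }
  }

  if (state == "unbound") {
    segs <- dplyr::bind_rows(
      linker_rows("linker_5p"),
      segment_spec("ssDNA", n_nt * ssdna_rise, ssdna_kuhn),
      linker_rows("linker_3p")
    )
  } else {
    degenerate <- binding_region_nt == 0 && endotoxin_length == 0
    if (!degenerate &&
        (endotoxin_length < 2 || endotoxin_length > 4)) {
      stop("bound-state `endotoxin_length` must lie in [2, 4] nm ",
           "(reported endotoxin dimension range)", call. = FALSE)
    }
    if (binding_region_nt > n_nt) {
      stop("`binding_region_nt` exceeds sequence length", call. = FALSE)
    }
    if ((n_nt - binding_region_nt) %% 2 != 0) {
      stop("flanks must be of equal length: `length(sequence) - ",
           "binding_region_nt` must be even", call. = FALSE)
    }
    flank_nt <- (n_nt - binding_region_nt) / 2
    if (binding_region_nt > 0) {
      core <- substr(sequence, flank_nt + 1, flank_nt + binding_region_nt)
      if (!grepl(core, sequence, fixed = TRUE)) {
        stop("binding region not present in sequence", call. = FALSE)
      }
    }
    complex_row <- if (endotoxin_length > 0) {
      segment_spec("complex", endotoxin_length, rigid = TRUE)
    } else {
      NULL
    }
    flank_row <- function(lab) {
      if (flank_nt > 0) segment_spec(lab, flank_nt * ssdna_rise, ssdna_kuhn) else NULL
    }
    segs <- dplyr::bind_rows(
      linker_rows("linker_5p"),
      flank_row("ssDNA_5p"),
      complex_row,
      flank_row("ssDNA_3p"),
      linker_rows("linker_3p")
    )
  }

  out <- structure(
    list(
      segments = segs,
      state = state,
      endotoxin_length = if (state == "bound") endotoxin_length else NA_real_,
      sequence = sequence,
      total_contour = sum(segs$contour_length)
    ),
    class = "tether_spec"
  )
  out
}

#' @export
print.tether_spec <- function(x, ...) {
  cat(sprintf("<tether_spec: %s, %d segments, total contour %.2f nm>\n",
              x$state, nrow(x$segments), x$total_contour))
  print(x$segments)
  invisible(x)
}

# Link lengths (nm) of the freely-jointed discretisation: rigid segments are
# one rod; a flexible segment of contour Lc and Kuhn length b becomes
# round(Lc/b) links (at least 1) of equal length preserving Lc.
.tether_links <- function(spec) {
  unlist(purrr::pmap(spec$segments, function(label, contour_length,
                                             kuhn_length, rigid) {
    if (rigid) {
      contour_length
    } else {
      n <- max(1L, round(contour_length / kuhn_length))
      rep(contour_length / n, n)
    }
  }))
}

#' Sample equilibrium nanoparticle heights by Monte Carlo
#'
#' Each chain is a freely jointed walk over the tether's Kuhn links (rigid
#' segments as single rods), every link direction uniform on the sphere.
#' Because all constraints act on z only and the z-component of an
#' isotropic unit vector is uniform on \[-1, 1\], only z-components are
#' sampled. A conformation is accepted when every chain node satisfies
#' z >= 0 (film impenetrability); the particle, attached at its lowest
#' pole, then automatically satisfies the sphere-film constraint because
#' the gap equals the terminal node height. Rejected conformations are
#' resampled until exactly `n_chains` survive.
#'
#' @param spec A [build_tether_spec()] object.
#' @param particle A [particle_spec()]; carried as metadata (the sphere
#'   constraint coincides with the terminal-node constraint under the
#'   lowest-pole attachment convention).
#' @param n_chains Number of accepted chains to return.
#' @param seed Integer RNG seed (required).
#' @param constraint `"all_nodes"` (default; film excludes every node) or
#'   `"end_only"` (only the attachment point is restricted to z >= 0;
#'   useful for analytic cross-checks).
#' @return A `position_ensemble`: tibble with columns `chain`, `z_nm`, and
#'   attributes `seed`, `n_chains`, `spec_hash`, `particle`, `spec`.
#' @export
sample_chain_conformations <- function(spec, particle = particle_spec(),
                                       n_chains, seed,
                                       constraint = c("all_nodes", "end_only")) {
  stopifnot(inherits(spec, "tether_spec"))
  constraint <- match.arg(constraint)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    stop("an explicit integer `seed` is required", call. = FALSE)
  }
  if (!is.numeric(n_chains) || n_chains < 1) {
    stop("`n_chains` must be >= 1", call. = FALSE)
  }
  n_chains <- as.integer(n_chains)
  flex <- spec$segments[!spec$segments$rigid, , drop = FALSE]
  if (nrow(flex) > 0 && spec$total_contour < max(flex$kuhn_length)) {
    stop("total contour is shorter than one Kuhn link", call. = FALSE)
  }
  lens <- .tether_links(spec)
  nl <- length(lens)

  set.seed(as.integer(seed))
  kept <- numeric(0)
  attempts <- 0
  while (length(kept) < n_chains) {
    m <- max(2L * (n_chains - length(kept)), 1000L)
    steps <- matrix(stats::runif(m * nl, -1, 1), m, nl)
    steps <- sweep(steps, 2, lens, `*`)
    cum <- steps
    if (nl > 1) {
      for (j in 2:nl) cum[, j] <- cum[, j - 1] + steps[, j]
    }
    ok <- if (constraint == "all_nodes") {
      rowSums(cum < 0) == 0
    } else {
      cum[, nl] >= 0
    }
    kept <- c(kept, cum[ok, nl])
    attempts <- attempts + m
    if (attempts >= 1e5 && length(kept) / attempts < 0.001) {
      stop(sprintf(
        paste0("rejection rate %.2f%% exceeds 99.9%% after %d attempts; ",
               "the boundary conditions leave almost no accessible ",
               "conformations for this tether"),
        100 * (1 - length(kept) / attempts), attempts), call. = FALSE)
    }
  }
  z <- kept[seq_len(n_chains)]

  out <- tibble::tibble(chain = seq_len(n_chains), z_nm = z)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_chains") <- n_chains
  attr(out, "spec_hash") <- rlang::hash(spec)
  attr(out, "particle") <- particle
  attr(out, "spec") <- spec
  class(out) <- c("position_ensemble", class(out))
  out
}

#' Summary statistics and height histogram of a position ensemble
#'
#' @param ensemble A `position_ensemble` (or any data frame with `z_nm`),
#'   or a bare numeric vector of heights in nm.
#' @param bin_width Histogram bin width, nm (> 0; default 0.25).
#' @return A list with `mean` (nm), `sd` (nm) and `histogram`, a tibble
#'   with columns `z_nm` (bin centers) and `density` (probability density,
#'   integrating to 1 over the support).
#' @export
summarize_z <- function(ensemble, bin_width = 0.25) {
  z <- if (is.numeric(ensemble)) ensemble else ensemble$z_nm
  if (is.null(z) || length(z) == 0) {
    stop("empty ensemble", call. = FALSE)
  }
  stopifnot(bin_width > 0)
  lo <- floor(min(z) / bin_width) * bin_width
  hi <- ceiling(max(z) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(z, breaks = breaks, plot = FALSE)
  list(
    mean = mean(z),
    sd = stats::sd(z),
    histogram = tibble::tibble(z_nm = h$mids, density = h$density)
  )
}
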
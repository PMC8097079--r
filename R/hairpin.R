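# Hairpin tension-probe mechanics: folding thermodynamics of the stem duplex
# and worm-like-chain stretching of the released single strand combine into
# the equilibrium opening force
#
#   F_1/2 = (dG_fold + dG_stretch) / dx,
#
# the force at which half of the hairpins are unfolded.

# Unified DNA nearest-neighbor parameters (1 M NaCl): dH in kcal/mol,
# dS in cal/(mol K), keyed by the 5'->3' dinucleotide of one strand.
# Complementary stacks share parameters (e.g. TT == AA read on the other
# strand), so all 16 dinucleotides are listed explicitly.
.nn_dH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.nn_dS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# duplex initiation per terminal base pair
.init_dH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.init_dS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)
# hairpin-loop closure penalty, dG at 37 C (kcal/mol) by loop length;
# treated as purely entropic so it scales with temperature
.loop_sizes <- c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30)
.loop_dG37 <- c(3.5, 3.5, 3.3, 4.0, 4.1, 4.1, 4.2, 4.3, 4.5, 4.6,
                4.7, 4.8, 4.9, 5.2, 5.6)

.check_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    stop("`", arg, "` must be a single nucleotide string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("invalid sequence: `", arg, "` may only contain A, C, G, T",
         call. = FALSE)
  }
  sequence
}

.revcomp <- function(sequence) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(sequence, "")[[1]]), collapse = ""))
}

.loop_penalty_dG37 <- function(loop_nt) {
  if (loop_nt < 3) stop("hairpin loops need at least 3 nt", call. = FALSE)
  if (loop_nt > 30) { # Jacobson-Stockmayer extrapolation beyond the table
    return(5.6 + 1.75 * 0.0019872 * 310.15 * log(loop_nt / 30))
  }
  stats::approx(.loop_sizes, .loop_dG37, xout = loop_nt)$y
}

#' Folding free energy of a hairpin stem duplex
#'
#' Nearest-neighbor free energy of the duplex formed by a hairpin stem at a
#' given temperature: the sum of unified stacking terms (from dH/dS so the
#' temperature dependence is explicit), the two duplex-initiation terms, and
#' (for `loop_nt >= 3`) the entropic hairpin-loop closure penalty.
#'
#' The returned value is signed: negative means the folded stem is stable.
#' [unzipping_force()] uses its magnitude as the unfolding free energy.
#'
#' @param stem_5to3 Stem sequence, 5' to 3', one strand of the duplex.
#' @param temperature Temperature in kelvin (default 310.15, i.e. 37 C).
#' @param loop_nt Hairpin loop length in nucleotides. `0` (default) scores the
#'   bare duplex with no loop closure term.
#' @return Free energy in pN nm (use [convert_energy()] for kcal/mol or kT).
#' @examples
#' fold_free_energy("GCGATTTTACACCGC", loop_nt = 6)
#' @seealso [unzipping_force()], [is_closed_at()]
#' @export
fold_free_energy <- function(stem_5to3, temperature = 310.15, loop_nt = 0) {
  stem <- .check_sequence(stem_5to3, "stem_5to3")
  stopifnot(temperature > 0)
  bases <- strsplit(stem, "")[[1]]
  n <- length(bases)
  dH <- sum(.init_dH[bases[1]], .init_dH[bases[n]])
  dS <- sum(.init_dS[bases[1]], .init_dS[bases[n]])
  if (n > 1) {
    stacks <- paste0(bases[-n], bases[-1])
    dH <- dH + sum(.nn_dH[stacks])
    dS <- dS + sum(.nn_dS[stacks])
  }
  if (loop_nt > 0) {
    # purely entropic: dG37 -> dS, rescaled by T
    dS <- dS - .loop_penalty_dG37(loop_nt) / 310.15 * 1000
  }
  dG_kcal <- dH - temperature * dS / 1000
  convert_energy(dG_kcal, "kcal_mol", "pN_nm")
}

#' Extension of single-stranded DNA at the unfolding transition
#'
#' `ssdna_extension()` gives the end-to-end extension of `n` released
#' nucleotides at the transition force, 0.44 nm (n - 1).
#' `opening_displacement()` subtracts the 2 nm width of the folded hairpin to
#' give the displacement gained on unfolding.
#'
#' @param n Number of released nucleotides (>= 1).
#' @return Length in nm.
#' @examples
#' ssdna_extension(36)      # 15.4
#' opening_displacement(36) # 13.4
#' @export
ssdna_extension <- function(n, rise_at_transition = 0.44) {
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  rise_at_transition * (n - 1)
}

#' @rdname ssdna_extension
#' @param rise_at_transition Extension per nucleotide at the transition
#'   force, nm (default 0.44).
#' @export
opening_displacement <- function(n, rise_at_transition = 0.44) {
  dx <- ssdna_extension(n, rise_at_transition) - 2
  if (any(dx <= 0)) {
    stop("probe too short: opening displacement 0.44 (n - 1) - 2 must be > 0",
         call. = FALSE)
  }
  dx
}

#' Worm-like-chain stretching free energy
#'
#' Free energy stored in a worm-like chain of contour length `L0` and
#' persistence length `Lp` stretched to end-to-end extension `x`:
#'
#'   dG = (kB T L0 / (4 Lp)) * r^2 (3 - 2 r) / (1 - r),  r = x / L0,
#'
#' which is the exact integral of the Marko-Siggia interpolation
#' force-extension relation from 0 to `x`.
#'
#' @param x Extension in nm, `0 <= x < L0`.
#' @param L0 Contour length in nm.
#' @param Lp Persistence length in nm (1.3 nm for ssDNA).
#' @param temperature Temperature in kelvin.
#' @return Energy in pN nm; zero at `x = 0`, diverging as `x -> L0`.
#' @examples
#' stretch_free_energy(15.4, L0 = 42.84, Lp = 1.3)
#' @export
stretch_free_energy <- function(x, L0, Lp = 1.3, temperature = 310.15) {
  if (any(Lp <= 0)) stop("`Lp` must be > 0", call. = FALSE)
  if (any(x < 0)) stop("`x` must be >= 0", call. = FALSE)
  if (any(x >= L0)) {
    stop("`x` must be below the contour length L0", call. = FALSE)
  }
  r <- x / L0
  kBT(temperature) * L0 / (4 * Lp) * r^2 * (3 - 2 * r) / (1 - r)
}

# locate the longest stem: pair of reverse-complementary runs separated by a
# loop of >= 3 nt; ties broken toward the longer loop-proximal match first
.find_stem <- function(sequence) {
  bases <- strsplit(sequence, "")[[1]]
  comp <- chartr("ACGT", "TGCA", sequence)
  cb <- strsplit(comp, "")[[1]]
  n <- length(bases)
  best <- NULL
  # a: index of last base of the 5' stem half; b: first base of 3' half
  for (a in seq_len(n - 4)) {
    for (b in (a + 4):n) {
      k <- 0
      while (a - k >= 1 && b + k <= n && bases[a - k] == cb[b + k]) {
        k <- k + 1
      }
      if (k >= 2 && b - a - 1 >= 3) {
        if (is.null(best) || k > best$len) {
          best <- list(start = a - k + 1, len = k, loop = b - a - 1)
        }
      }
    }
  }
  if (is.null(best)) {
    stop("no hairpin stem (>= 2 bp with >= 3 nt loop) found in sequence",
         call. = FALSE)
  }
  best
}

#' Define a DNA hairpin tension sensor
#'
#' Bundles a probe sequence with its stem/loop decomposition and the
#' mechanical parameters of the unzipping-force model. If `stem_start` /
#' `stem_bp` / `loop_nt` are not given, the stem is auto-detected as the
#' longest pair of reverse-complementary runs enclosing a loop of at least
#' 3 nt.
#'
#' The number of nucleotides released on unfolding is
#' `released_nt = 2 * stem_bp + loop_nt`. The contour length used for the
#' stretching free energy defaults to `contour_per_nt` times the full strand
#' length: after unfolding the entire probe strand is single-stranded in the
#' force path. Supply a sequence containing only stem and loop to recover a
#' released-segment contour length instead.
#'
#' @param sequence Probe sequence 5' to 3' (A/C/G/T only).
#' @param stem_start 1-based position of the first stem base (optional).
#' @param stem_bp Number of stem base pairs (optional, auto-detected).
#' @param loop_nt Loop length in nucleotides (optional, auto-detected).
#' @param temperature Temperature in kelvin (default 310.15 K = 37 C).
#' @param Lp Persistence length of ssDNA in nm (default 1.3).
#' @param rise_at_transition Extension per released nucleotide at the
#'   transition force, nm (default 0.44).
#' @param contour_per_nt Contour length per nucleotide of ssDNA, nm
#'   (default 0.63).
#' @return An object of class `hairpin_sensor`.
#' @examples
#' probe <- paste0(
#'   "TTTTATACATCTAGTTTTT", "GCGATTTTACACCGC", "TTTTTT",
#'   "GCGGTGTAAAATCGC", "TTTCTTCATTATT"
#' )
#' hairpin_sensor(probe)
#' @export
hairpin_sensor <- function(sequence, stem_start = NULL, stem_bp = NULL,
                           loop_nt = NULL, temperature = 310.15, Lp = 1.3,
                           rise_at_transition = 0.44, contour_per_nt = 0.63) {
  sequence <- .check_sequence(sequence)
  if (is.null(stem_start) || is.null(stem_bp) || is.null(loop_nt)) {
    stem <- .find_stem(sequence)
    stem_start <- stem$start
    stem_bp <- stem$len
    loop_nt <- stem$loop
  }
  stopifnot(
    stem_bp >= 1, loop_nt >= 3,
    0 < rise_at_transition, rise_at_transition <= contour_per_nt,
    Lp > 0, temperature > 0
  )
  stem1 <- substr(sequence, stem_start, stem_start + stem_bp - 1)
  stem2 <- substr(sequence, stem_start + stem_bp + loop_nt,
                  stem_start + 2 * stem_bp + loop_nt - 1)
  if (nchar(stem2) != stem_bp || stem2 != .revcomp(stem1)) {
    stop("stem halves are not reverse complements of each other",
         call. = FALSE)
  }
  structure(
    list(
      sequence = sequence,
      stem_start = stem_start,
      stem = stem1,
      stem_bp = stem_bp,
      loop_nt = loop_nt,
      released_nt = 2L * stem_bp + loop_nt,
      temperature = temperature,
      Lp = Lp,
      rise_at_transition = rise_at_transition,
      contour_per_nt = contour_per_nt
    ),
    class = "hairpin_sensor"
  )
}

#' @export
print.hairpin_sensor <- function(x, ...) {
  cat("<hairpin_sensor> ", nchar(x$sequence), " nt, stem ", x$stem_bp,
      " bp + loop ", x$loop_nt, " nt (", x$released_nt,
      " nt released), T = ", x$temperature, " K\n", sep = "")
  invisible(x)
}

#' Equilibrium unzipping force of a hairpin sensor
#'
#' Computes the full energy budget of hairpin opening: the folding free
#' energy of the stem (nearest-neighbor model, or an externally supplied
#' value), the worm-like-chain free energy of stretching the single strand
#' to its transition extension, and the opening displacement; their ratio is
#' the equilibrium half-opening force
#' `F_1/2 = (dG_fold + dG_stretch) / dx`.
#'
#' @param sensor A [hairpin_sensor()].
#' @param dG_fold Optional externally computed unfolding free energy
#'   (magnitude, pN nm), e.g. from a full secondary-structure prediction
#'   tool; replaces the internal nearest-neighbor value.
#' @param L0 Optional contour-length override in nm; default
#'   `contour_per_nt * nchar(sequence)`.
#' @return An `energy_budget` object: a list with `dG_fold`, `dG_stretch`
#'   (pN nm), `x`, `L0`, `dx` (nm) and `F_half` (pN); has [generics::tidy()]
#'   and [generics::glance()] methods.
#' @examples
#' probe <- paste0(
#'   "TTTTATACATCTAGTTTTT", "GCGATTTTACACCGC", "TTTTTT",
#'   "GCGGTGTAAAATCGC", "TTTCTTCATTATT"
#' )
#' unzipping_force(hairpin_sensor(probe))
#' @export
unzipping_force <- function(sensor, dG_fold = NULL, L0 = NULL) {
  stopifnot(inherits(sensor, "hairpin_sensor"))
  if (is.null(dG_fold)) {
    dG <- fold_free_energy(sensor$stem, sensor$temperature, sensor$loop_nt)
    if (dG >= 0) {
      stop("hairpin is not stable at this temperature; no unzipping force",
           call. = FALSE)
    }
    dG_fold <- -dG
  }
  stopifnot(dG_fold >= 0)
  n <- sensor$released_nt
  x <- ssdna_extension(n, sensor$rise_at_transition)
  dx <- opening_displacement(n, sensor$rise_at_transition)
  if (is.null(L0)) L0 <- sensor$contour_per_nt * nchar(sensor$sequence)
  dG_stretch <- stretch_free_energy(x, L0, sensor$Lp, sensor$temperature)
  structure(
    list(
      dG_fold = dG_fold, dG_stretch = dG_stretch,
      x = x, L0 = L0, dx = dx,
      F_half = (dG_fold + dG_stretch) / dx,
      temperature = sensor$temperature
    ),
    class = "energy_budget"
  )
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf(
    paste0("<energy_budget> F_1/2 = %.2f pN\n",
           "  dG_fold = %.1f pN nm (%.2f kcal/mol), dG_stretch = %.1f pN nm\n",
           "  x = %.2f nm, L0 = %.2f nm, dx = %.2f nm\n"),
    x$F_half, x$dG_fold, convert_energy(x$dG_fold, "pN_nm", "kcal_mol"),
    x$dG_stretch, x$x, x$L0, x$dx
  ))
  invisible(x)
}

#' @export
tidy.energy_budget <- function(x, ...) {
  tibble::tibble(
    term = c("dG_fold", "dG_stretch", "x", "L0", "dx", "F_half"),
    estimate = c(x$dG_fold, x$dG_stretch, x$x, x$L0, x$dx, x$F_half),
    unit = c("pN nm", "pN nm", "nm", "nm", "nm", "pN")
  )
}

#' @export
glance.energy_budget <- function(x, ...) {
  tibble::tibble(
    F_half = x$F_half,
    dG_fold = x$dG_fold,
    dG_stretch = x$dG_stretch,
    dx = x$dx,
    temperature = x$temperature
  )
}

#' Is a hairpin sensor closed at a given temperature?
#'
#' A stem-duplex proxy for full secondary-structure prediction: the sensor
#' is called closed when the nearest-neighbor folding free energy of its
#' stem, including the hairpin-loop penalty, is negative (stabilizing) at
#' the given temperature. The margin is the magnitude of that free energy.
#'
#' @param sensor A [hairpin_sensor()].
#' @param temperature Temperature in kelvin (defaults to the sensor's).
#' @return A list with `closed` (logical) and `margin` (pN nm, positive when
#'   closed).
#' @export
is_closed_at <- function(sensor, temperature = sensor$temperature) {
  stopifnot(inherits(sensor, "hairpin_sensor"))
  dG <- fold_free_energy(sensor$stem, temperature, sensor$loop_nt)
  list(closed = dG < 0, margin = -dG)
}
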
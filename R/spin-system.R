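#' Define a nuclear spin coupled to one of the two radical electrons
#'
#' @param label Character label for the nucleus (e.g. `"N5"`).
#' @param spin Nuclear spin quantum number I; a non-negative half-integer
#'   (1/2, 1, 3/2, ...).
#' @param coupling_uT Isotropic hyperfine coupling constant a, in microtesla.
#' @param electron Which radical electron the nucleus couples to, `"A"` or
#'   `"B"`.
#' @return An object of class `rp_nucleus`.
#' @examples
#' nucleus("N5", spin = 1, coupling_uT = 523, electron = "A")
#' @export
nucleus <- function(label, spin, coupling_uT, electron = c("A", "B")) {
  electron <- match.arg(electron)
  if (!is.numeric(spin) || length(spin) != 1L || spin < 0 ||
      abs(2 * spin - round(2 * spin)) > 1e-12) {
    stop("'spin' must be a non-negative half-integer (1/2, 1, 3/2, ...)",
         call. = FALSE)
  }
  if (!is.numeric(coupling_uT) || length(coupling_uT) != 1L ||
      !is.finite(coupling_uT)) {
    stop("'coupling_uT' must be a finite number", call. = FALSE)
  }
  structure(
    list(label = as.character(label), spin = spin,
         coupling_uT = coupling_uT, electron = electron,
         multiplicity = as.integer(round(2 * spin + 1))),
    class = "rp_nucleus"
  )
}

#' Construct a two-electron/N-nucleus radical pair spin system
#'
#' The system comprises two unpaired electron spins (one per radical, labelled
#' A and B) and any number of nuclear spins, each coupled isotropically to one
#' electron.  The pair is always taken to be born in the electron singlet
#' state.  Operators are embedded in the tensor-product space in the fixed
#' order electron A, electron B, then nuclei in declaration order, with
#' magnetic quantum numbers descending within each factor.
#'
#' @param name Name of the system.
#' @param nuclei A list of [nucleus()] objects (may be empty).
#' @return An object of class `radical_pair` with components `name`, `nuclei`,
#'   `dims` (per-factor multiplicities), `dim` (Hilbert-space dimension
#'   \eqn{4 \prod_i (2 I_i + 1)}) and `M` (number of nuclear spin
#'   configurations \eqn{\prod_i (2 I_i + 1)}).
#' @examples
#' sys <- radical_pair_system("FAD-Z", list(
#'   nucleus("N5", 1, 523, "A"),
#'   nucleus("N10", 1, 189, "A")))
#' sys$dim  # 36
#' @seealso [rp_preset()] for the bundled cryptochrome-like presets.
#' @export
radical_pair_system <- function(name, nuclei = list()) {
  if (inherits(nuclei, "rp_nucleus")) nuclei <- list(nuclei)
  if (!all(vapply(nuclei, inherits, logical(1), "rp_nucleus"))) {
    stop("'nuclei' must be a list of nucleus() objects", call. = FALSE)
  }
  mults <- vapply(nuclei, `[[`, integer(1), "multiplicity")
  structure(
    list(name = as.character(name), nuclei = nuclei,
         dims = c(2L, 2L, mults),
         dim = as.integer(4L * prod(mults)),
         M = as.integer(prod(mults))),
    class = "radical_pair"
  )
}

#' @export
print.radical_pair <- function(x, ...) {
  cat(sprintf("<radical_pair> %s\n", x$name))
  cat(sprintf("  electrons: 2 (A, B), singlet-born; nuclei: %d\n",
              length(x$nuclei)))
  for (nuc in x$nuclei) {
    cat(sprintf("    %-4s I = %g, a = %g uT, electron %s\n",
                nuc$label, nuc$spin, nuc$coupling_uT, nuc$electron))
  }
  cat(sprintf("  Hilbert dimension %d, nuclear configurations M = %d\n",
              x$dim, x$M))
  invisible(x)
}

#' Load a radical pair system from a JSON or YAML configuration file
#'
#' The file must contain a `name` and a `nuclei` array, each entry having
#' `label`, `spin`, `coupling_uT` and `electron` fields.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [radical_pair_system()] object.
#' @examples
#' path <- system.file("extdata", "fad-z.json", package = "radicalpair")
#' read_radical_pair(path)
#' @export
read_radical_pair <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  if (is.null(cfg$name)) stop("config lacks a 'name' field", call. = FALSE)
  nuclei <- lapply(cfg$nuclei, function(n) {
    nucleus(n$label, n$spin, n$coupling_uT, n$electron)
  })
  radical_pair_system(cfg$name, nuclei)
}

#' Bundled radical pair presets
#'
#' Two cryptochrome-like presets are shipped with the package:
#' \describe{
#'   \item{`"FAD-TrpH"`}{the flavin/tryptophan pair with the three nitrogens
#'     carrying the largest isotropic hyperfine couplings: N5 and N10 of the
#'     flavin radical anion (523 and 189 uT, electron A) and N1 of the
#'     tryptophan cation radical (322 uT, electron B).  Hilbert dimension
#'     108, M = 27.}
#'   \item{`"FAD-Z"`}{the same flavin radical paired with a hypothetical
#'     partner radical Z with no hyperfine interactions at all.  Dimension
#'     36, M = 9.}
#' }
#'
#' @param name Preset name, `"FAD-TrpH"` or `"FAD-Z"` (case-insensitive).
#' @return A [radical_pair_system()] object.
#' @examples
#' rp_preset("FAD-TrpH")
#' @export
rp_preset <- function(name = c("FAD-TrpH", "FAD-Z")) {
  name <- match.arg(tolower(name[1L]), c("fad-trph", "fad-z"))
  file <- if (name == "fad-trph") "fad-trph.json" else "fad-z.json"
  read_radical_pair(system.file("extdata", file, package = "radicalpair",
                                mustWork = TRUE))
}

#' Generate a random small radical pair system
#'
#' Draws a spin system with 1--3 nuclei of spin 1/2 or 1 and hyperfine
#' couplings uniform on (50, 600) uT, each assigned to electron A or B at
#' random.  Intended for property-based testing of invariants that must hold
#' for every system.
#'
#' @param n_nuclei Number of nuclei; if `NULL`, drawn uniformly from 1:3.
#' @param max_nuclei Upper bound when `n_nuclei` is drawn.
#' @return A [radical_pair_system()] object.
#' @examples
#' set.seed(1)
#' random_radical_pair()
#' @export
random_radical_pair <- function(n_nuclei = NULL, max_nuclei = 3L) {
  if (is.null(n_nuclei)) n_nuclei <- sample.int(max_nuclei, 1L)
  nuclei <- lapply(seq_len(n_nuclei), function(i) {
    nucleus(paste0("n", i),
            spin = sample(c(0.5, 1), 1L),
            coupling_uT = stats::runif(1L, 50, 600),
            electron = sample(c("A", "B"), 1L))
  })
  radical_pair_system(sprintf("random-%d", n_nuclei), nuclei)
}

#' Reaction and relaxation kinetics of the radical pair
#'
#' Both spin-selective reaction channels (singlet and triplet) share a single
#' first-order rate constant k, so the radical pair lifetime is \eqn{\tau =
#' 1/k} (the "exponential model").  Spin relaxation is phenomenological: an
#' exponential decay at rate r towards the statistical 1:3 singlet:triplet
#' mixture.
#'
#' @param k First-order reaction rate constant, s\eqn{^{-1}}.  Exactly one of
#'   `k` and `tau` must be given.
#' @param tau Radical pair lifetime 1/k, s.
#' @param r Spin relaxation rate constant, s\eqn{^{-1}} (>= 0).
#' @return An object of class `reaction_kinetics` with fields `k`, `r`, `tau`.
#' @examples
#' reaction_kinetics(tau = 1e-6, r = 1e6)
#' @export
reaction_kinetics <- function(k = NULL, tau = NULL, r = 0) {
  if (is.null(k) == is.null(tau)) {
    stop("specify exactly one of 'k' and 'tau'", call. = FALSE)
  }
  if (is.null(k)) {
    if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
    k <- 1 / tau
  }
  if (!is.numeric(k) || k <= 0) stop("'k' must be positive", call. = FALSE)
  if (!is.numeric(r) || r < 0) stop("'r' must be non-negative", call. = FALSE)
  structure(list(k = k, r = r, tau = 1 / k), class = "reaction_kinetics")
}

#' @export
print.reaction_kinetics <- function(x, ...) {
  cat(sprintf("<reaction_kinetics> k = %g /s (tau = %g s), r = %g /s\n",
              x$k, x$tau, x$r))
  invisible(x)
}
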
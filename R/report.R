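# Summary-table and figure-data generation, plus text serialisation of
# sweep results.  The CSV format is two numeric columns preceded by
# '#'-prefixed metadata lines, diff-friendly and round-trippable at full
# double precision; a JSON sidecar carries the same content.

.default_run_config <- function() {
  list(r = 1e6, B0_uT = 50, B1_uT = 1, dB0_uT = -1,
       k = 1e6, dk = 1e3, dr = 1e3,
       tau_range = c(1e-9, 1e-3), points_per_decade = 25L,
       fig2_taus = c(30e-9, 100e-9, 300e-9, 1e-6, 3e-6, 10e-6, 100e-6),
       fig2_B_max_uT = 5000, fig2_B_points = 201L)
}

.merge_config <- function(config) {
  out <- .default_run_config()
  for (nm in names(config)) out[[nm]] <- config[[nm]]
  out
}

#' Summary table of weak-field and temperature sensitivities
#'
#' Recomputes, for the two bundled radical pair presets, the six headline
#' quantities: the lifetime-extremised ELF effect (B1 = 1 uT), the
#' lifetime-extremised geomagnetic effect (dB0 = -1 uT), their ratio Omega,
#' and the three temperature effects (k only, r only, and both rates
#' perturbed by 0.1%).  All mfe/Te values are in ppm; Omega is
#' dimensionless.  The print method rounds to 2 significant figures; the
#' returned data frame keeps full precision.
#'
#' @param config Optional named list overriding the defaults: `r` (1e6 /s),
#'   `B0_uT` (50), `B1_uT` (1), `dB0_uT` (-1), `k` (1e6 /s), `dk`, `dr`
#'   (1e3 /s), `tau_range` (1 ns to 1 ms), `points_per_decade` (25).
#' @param systems List of two [radical_pair_system()] objects; defaults to
#'   the FAD-TrpH and FAD-Z presets.
#' @return A data frame of class `rp_table` with columns `quantity`,
#'   `conditions`, and one value column per system.
#' @examples
#' \donttest{
#' run_table1()
#' }
#' @export
run_table1 <- function(config = list(), systems = NULL) {
  cfg <- .merge_config(config)
  if (is.null(systems)) systems <- list(rp_preset("FAD-TrpH"), rp_preset("FAD-Z"))
  stopifnot(cfg$r > 0, cfg$k > 0)
  proto <- field_protocol(cfg$B0_uT, cfg$B1_uT, cfg$dB0_uT)
  kin <- reaction_kinetics(k = cfg$k, r = cfg$r)

  cols <- lapply(systems, function(sys) {
    cache <- .spectral_cache(sys)
    elf <- lifetime_extremum(sys, cfg$r, proto, "elf", cfg$tau_range,
                             cfg$points_per_decade, cache = cache)
    gmf <- lifetime_extremum(sys, cfg$r, proto, "gmf", cfg$tau_range,
                             cfg$points_per_decade, cache = cache)
    te_k  <- temperature_effect(sys, kin, rate_perturbation(dk = cfg$dk),
                                cfg$B0_uT, cache = cache)
    te_r  <- temperature_effect(sys, kin, rate_perturbation(dr = cfg$dr),
                                cfg$B0_uT, cache = cache)
    te_kr <- temperature_effect(sys, kin,
                                rate_perturbation(dk = cfg$dk, dr = cfg$dr),
                                cfg$B0_uT, cache = cache)
    c(elf$mfe$ppm, gmf$mfe$ppm, gmf$mfe$value / elf$mfe$value,
      te_k * 1e6, te_r * 1e6, te_kr * 1e6)
  })

  out <- data.frame(
    quantity = c("mfeELFmax_ppm", "mfeGMFmax_ppm", "Omega",
                 "Te_dk_ppm", "Te_dr_ppm", "Te_dk_dr_ppm"),
    conditions = c(sprintf("B1 = %g uT", cfg$B1_uT),
                   sprintf("dB0 = %g uT", cfg$dB0_uT),
                   "mfeGMFmax / mfeELFmax",
                   sprintf("dk = %g /s", cfg$dk),
                   sprintf("dr = %g /s", cfg$dr),
                   sprintf("dk = dr = %g /s", cfg$dk)),
    stringsAsFactors = FALSE
  )
  for (j in seq_along(systems)) out[[systems[[j]]$name]] <- cols[[j]]
  class(out) <- c("rp_table", "data.frame")
  attr(out, "config") <- cfg
  out
}

#' @export
print.rp_table <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# ---- sweep serialisation --------------------------------------------------

#' Write and read sweep results as annotated CSV
#'
#' `write_sweep_csv()` writes a [mfe_vs_lifetime()]/[phi_vs_field()] result
#' as a two-column CSV with `#`-prefixed metadata header lines;
#' `read_sweep_csv()` parses such a file back into a `sweep_result`.  Numeric
#' columns are written with 17 significant digits so the round trip is exact
#' at 15 significant digits.
#'
#' @param sweep A `sweep_result`.
#' @param path Output file path.
#' @return `write_sweep_csv()` returns `path` invisibly; `read_sweep_csv()`
#'   returns a `sweep_result`.
#' @examples
#' sw <- phi_vs_field(rp_preset("FAD-Z"), reaction_kinetics(tau = 1e-6, r = 1e6),
#'                    c(0, 50, 500))
#' f <- tempfile(fileext = ".csv")
#' write_sweep_csv(sw, f)
#' read_sweep_csv(f)$values
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  meta <- vapply(names(sweep$metadata), function(nm) {
    sprintf("# %s: %s", nm, paste(format(sweep$metadata[[nm]], digits = 17),
                                  collapse = " "))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# radicalpair sweep", meta,
               sprintf("# axis: %s", sweep$axis_name)), con)
  writeLines(paste(sweep$axis_name, "value", sep = ","), con)
  writeLines(sprintf("%.17g,%.17g", sweep$axis_values, sweep$values), con)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines[-1]) {
    m <- regmatches(ln, regexec("^# ([^:]+): (.*)$", ln))[[1]]
    if (length(m) == 3L) {
      val <- suppressWarnings(as.numeric(strsplit(m[3], " ")[[1]]))
      meta[[m[2]]] <- if (anyNA(val)) m[3] else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"))
  axis_name <- meta[["axis"]]
  meta[["axis"]] <- NULL
  .new_sweep_result(axis_name, dat[[1]], dat[[2]], meta)
}

#' Write a sweep result as JSON
#'
#' JSON sidecar companion to [write_sweep_csv()], with fields `axis_name`,
#' `axis_values`, `values` and `metadata`.
#'
#' @inheritParams write_sweep_csv
#' @return `path`, invisibly.
#' @export
write_sweep_json <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  jsonlite::write_json(
    list(axis_name = sweep$axis_name, axis_values = sweep$axis_values,
         values = sweep$values, metadata = sweep$metadata),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- figure data ----------------------------------------------------------

.fig_tau_grid <- function(cfg) {
  lo <- log10(cfg$tau_range[1]); hi <- log10(cfg$tau_range[2])
  n <- max(2L, ceiling((hi - lo) * cfg$points_per_decade) + 1L)
  10^seq(lo, hi, length.out = n)
}

.write_curve <- function(sweep, dir, stem) {
  csv <- file.path(dir, paste0(stem, ".csv"))
  write_sweep_csv(sweep, csv)
  write_sweep_json(sweep, file.path(dir, paste0(stem, ".json")))
  csv
}

#' Regenerate the data behind the field-sweep and lifetime-sweep figures
#'
#' Writes one CSV (plus a JSON sidecar) per curve into `out_dir`:
#' \describe{
#'   \item{`fig2`}{\eqn{\Phi_T} vs B0 (0 to 5 mT) for seven lifetimes between
#'     30 ns and 100 us, relaxation time 1 us.}
#'   \item{`fig2s1`}{the same with relaxation time 0.1 us.}
#'   \item{`fig4`}{ELF (Taylor) and geomagnetic (linearised) effects in ppm
#'     vs lifetime (1 ns to 1 ms) for both presets.}
#'   \item{`fig4s1`}{Taylor vs phase-average quadrature ELF curves
#'     (FAD-TrpH).}
#'   \item{`fig4s2`}{`fig4` with relaxation rate 1e7 /s (both effects change
#'     sign).}
#'   \item{`fig4s3`}{FAD-TrpH ELF and GMF curves at B0 = 25, 50 and 65 uT.}
#' }
#'
#' @param figure_id One of `"fig2"`, `"fig2s1"`, `"fig4"`, `"fig4s1"`,
#'   `"fig4s2"`, `"fig4s3"`.
#' @param config Optional overrides as in [run_table1()]; `points_per_decade`
#'   and `fig2_B_points` control grid density.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of CSV paths, invisibly.
#' @examples
#' \donttest{
#' run_figure_data("fig4", config = list(points_per_decade = 5),
#'                 out_dir = tempdir())
#' }
#' @export
run_figure_data <- function(figure_id, config = list(), out_dir = ".") {
  valid <- c("fig2", "fig2s1", "fig4", "fig4s1", "fig4s2", "fig4s3")
  if (!is.character(figure_id) || length(figure_id) != 1L ||
      !figure_id %in% valid) {
    stop("unknown figure id; expected one of: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  cfg <- .merge_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  trph <- rp_preset("FAD-TrpH")
  fadz <- rp_preset("FAD-Z")
  files <- character(0)

  if (figure_id %in% c("fig2", "fig2s1")) {
    r <- if (figure_id == "fig2") cfg$r else 1e7
    B_grid <- seq(0, cfg$fig2_B_max_uT, length.out = cfg$fig2_B_points)
    cache <- .spectral_cache(trph)
    for (tau in cfg$fig2_taus) {
      sw <- phi_vs_field(trph, reaction_kinetics(tau = tau, r = r), B_grid,
                         cache = cache)
      files <- c(files, .write_curve(
        sw, out_dir, sprintf("%s_phi_vs_B0_tau_%gus", figure_id, tau * 1e6)))
    }
    return(invisible(files))
  }

  taus <- .fig_tau_grid(cfg)
  if (figure_id %in% c("fig4", "fig4s2")) {
    r <- if (figure_id == "fig4") cfg$r else 1e7
    for (sys in list(trph, fadz)) {
      cache <- .spectral_cache(sys)
      proto <- field_protocol(cfg$B0_uT, cfg$B1_uT, cfg$dB0_uT)
      for (mode in c("elf", "gmf")) {
        sw <- mfe_vs_lifetime(sys, r, proto, taus, mode, cache = cache)
        files <- c(files, .write_curve(
          sw, out_dir, sprintf("%s_mfe_%s_%s", figure_id, mode,
                               tolower(sys$name))))
      }
    }
  } else if (figure_id == "fig4s1") {
    cache <- .spectral_cache(trph)
    proto <- field_protocol(cfg$B0_uT, cfg$B1_uT, cfg$dB0_uT)
    for (method in c("taylor", "quadrature")) {
      sw <- mfe_vs_lifetime(trph, cfg$r, proto, taus, "elf", method,
                            cache = cache)
      files <- c(files, .write_curve(
        sw, out_dir, sprintf("fig4s1_mfe_elf_%s", method)))
    }
  } else {  # fig4s3
    cache <- .spectral_cache(trph)
    for (B0 in c(25, 50, 65)) {
      proto <- field_protocol(B0, cfg$B1_uT, cfg$dB0_uT)
      for (mode in c("elf", "gmf")) {
        sw <- mfe_vs_lifetime(trph, cfg$r, proto, taus, mode, cache = cache)
        files <- c(files, .write_curve(
          sw, out_dir, sprintf("fig4s3_mfe_%s_B0_%guT", mode, B0)))
      }
    }
  }
  invisible(files)
}
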
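# Columnar text I/O (profiles, manifests, terms, key-value configs) and
# the end-to-end pipeline driver.
#
# Conventions, stated in every output header: Q in 1/A, energies in keV,
# intensities in 1/cm.

#' Read a 1-D scattering profile
#'
#' Whitespace-delimited text with at least three numeric columns
#' (Q [1/A], intensity [1/cm], sigma [1/cm]); `#` starts a comment. Rows
#' with NaN are dropped (count reported via message); Q is sorted
#' ascending with a warning if needed; non-positive sigma is an error
#' naming the offending line.
#'
#' @param path File path.
#' @return List with numeric vectors `q`, `intensity`, `sigma`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  stripped <- sub("#.*$", "", lines)
  data_idx <- which(nzchar(trimws(stripped)))
  if (length(data_idx) == 0L) stop("empty profile file: ", path,
                                   call. = FALSE)
  rows <- lapply(data_idx, function(i) {
    fields <- strsplit(trimws(stripped[i]), "[[:space:],]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 3L || any(is.na(vals[1:3]) & !is.nan(vals[1:3]))) {
      stop(sprintf("%s line %d: expected >= 3 numeric columns", path, i),
           call. = FALSE)
    }
    c(line = i, vals[1:3])
  })
  m <- do.call(rbind, rows)
  nan_rows <- apply(m[, 2:4, drop = FALSE], 1, function(r) any(is.nan(r)))
  if (any(nan_rows)) {
    message("read_profile: dropped ", sum(nan_rows), " NaN row(s) from ",
            path)
    m <- m[!nan_rows, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no usable rows in ", path, call. = FALSE)
  bad_sigma <- which(m[, 4] <= 0)
  if (length(bad_sigma) > 0L) {
    stop(sprintf("%s line %d: non-positive sigma", path,
                 m[bad_sigma[1], 1]), call. = FALSE)
  }
  if (is.unsorted(m[, 2], strictly = FALSE)) {
    warning("profile ", path, " was not sorted in Q; sorting",
            call. = FALSE)
    m <- m[order(m[, 2]), , drop = FALSE]
  }
  list(q = unname(m[, 2]), intensity = unname(m[, 3]),
       sigma = unname(m[, 4]))
}

#' Write a 1-D scattering profile
#'
#' @param path Output path.
#' @param q,intensity,sigma Equal-length numeric vectors.
#' @param header Optional extra comment lines.
#' @export
write_profile <- function(path, q, intensity, sigma, header = NULL) {
  stopifnot(length(q) == length(intensity), length(q) == length(sigma))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# 1-D scattering profile",
               "# columns: Q_invA  intensity_invcm  sigma_invcm",
               if (!is.null(header)) paste("#", header)), con)
  writeLines(sprintf("%.12g %.12g %.12g", q, intensity, sigma), con)
  invisible(path)
}

#' Write a multi-energy dataset as per-energy profiles plus a manifest
#'
#' Emits one 3-column profile file per energy and a manifest listing
#' (filename, energy) pairs together with the resonant element and the
#' dispersion-table path -- the on-disk interchange format between the
#' generator and the decomposition stage.
#'
#' @param dataset An [energy_scan()].
#' @param dir Output directory (created if needed).
#' @param stem Filename stem for the profiles.
#' @param dispersion_path Path recorded in the manifest for the dispersion
#'   table; if `NULL` the table is written alongside as
#'   `<stem>_dispersion.txt`.
#' @return Path of the manifest file.
#' @export
write_energy_scan <- function(dataset, dir, stem = "profile",
                              dispersion_path = NULL) {
  stopifnot(inherits(dataset, "energy_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(dispersion_path)) {
    dispersion_path <- paste0(stem, "_dispersion.txt")
    tab <- dataset$dispersion
    con <- file(file.path(dir, dispersion_path), "w")
    writeLines(c(sprintf("# dispersion table: %s, edge %.6g keV",
                         tab$element, tab$edge_energy),
                 "# columns: energy_keV f_prime f_doubleprime"), con)
    writeLines(sprintf("%.12g %.12g %.12g", tab$energy, tab$f_prime,
                       tab$f_doubleprime), con)
    close(con)
  }
  files <- sprintf("%s_e%02d.dat", stem, seq_along(dataset$energies))
  for (i in seq_along(dataset$energies)) {
    write_profile(file.path(dir, files[i]), dataset$q_grid,
                  dataset$intensity[i, ], dataset$sigma[i, ],
                  header = sprintf("energy %.6f keV", dataset$energies[i]))
  }
  manifest <- file.path(dir, paste0(stem, "_manifest.txt"))
  con <- file(manifest, "w")
  on.exit(close(con))
  writeLines(c("# ASAXS manifest: Q in 1/A, energies in keV, I in 1/cm",
               paste("element", dataset$resonant_element),
               sprintf("edge_energy %.6g", dataset$dispersion$edge_energy),
               paste("dispersion", dispersion_path),
               sprintf("profile %s %.6f", files, dataset$energies)), con)
  manifest
}

#' Read a manifest and its profiles into a multi-energy dataset
#'
#' @param manifest Path to a manifest written by [write_energy_scan()] (or
#'   hand-authored in the same format). Relative profile and dispersion
#'   paths resolve against the manifest's directory.
#' @return An [energy_scan()].
#' @export
read_energy_scan <- function(manifest) {
  dir <- dirname(manifest)
  lines <- readLines(manifest)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[[:space:]]+")
  key <- vapply(kv, `[`, character(1), 1)
  element <- kv[[match("element", key)]][2]
  edge <- as.numeric(kv[[match("edge_energy", key)]][2])
  disp_path <- kv[[match("dispersion", key)]][2]
  if (!file.exists(disp_path)) disp_path <- file.path(dir, disp_path)
  prof <- kv[key == "profile"]
  if (length(prof) == 0L) stop("manifest lists no profiles", call. = FALSE)
  files <- vapply(prof, `[`, character(1), 2)
  energies <- as.numeric(vapply(prof, `[`, character(1), 3))
  if (anyDuplicated(energies)) {
    stop("manifest energies must be unique", call. = FALSE)
  }
  paths <- ifelse(file.exists(files), files, file.path(dir, files))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing profile file(s): ", paste(files[missing], collapse = ", "),
         call. = FALSE)
  }
  table <- read_dispersion_table(disp_path, element, edge)
  profs <- lapply(paths, read_profile)
  q <- profs[[1]]$q
  for (p in profs) {
    if (length(p$q) != length(q) || any(abs(p$q - q) > 1e-9 * max(q))) {
      stop("profiles do not share one Q grid", call. = FALSE)
    }
  }
  ord <- order(energies)
  energy_scan(q, energies[ord],
              do.call(rbind, lapply(profs[ord], `[[`, "intensity")),
              do.call(rbind, lapply(profs[ord], `[[`, "sigma")),
              element, table)
}

#' Write decomposed scattering terms
#'
#' 7-column text: Q, S, sigma_S, C, sigma_C, R, sigma_R.
#'
#' @param path Output path.
#' @param terms A [scattering_terms()] with uncertainties.
#' @export
write_terms <- function(path, terms) {
  stopifnot(inherits(terms, "scattering_terms"),
            !is.null(terms$sigma_saxs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# Stuhrmann scattering terms: Q in 1/A, terms in 1/cm",
               "# columns: Q S sigma_S C sigma_C R sigma_R"), con)
  writeLines(sprintf(paste(rep("%.12g", 7), collapse = " "),
                     terms$q_grid, terms$saxs_term, terms$sigma_saxs,
                     terms$cross_term, terms$sigma_cross,
                     terms$resonant_term, terms$sigma_resonant), con)
  invisible(path)
}

#' Read decomposed scattering terms
#'
#' @param path Path to a file written by [write_terms()].
#' @return A [scattering_terms()].
#' @export
read_terms <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("q", "s", "ss", "c", "sc", "r",
                                         "sr"))
  scattering_terms(tab$q, tab$s, tab$c, tab$r, sigma_saxs = tab$ss,
                   sigma_cross = tab$sc, sigma_resonant = tab$sr)
}

#' Read a key-value configuration file
#'
#' Lines of `key value` (or `key = value`), `#` comments. Values are
#' converted to numeric where possible. Later keys override earlier ones;
#' `defaults` and `overrides` layer below and above the file.
#'
#' @param path File path, or `NULL` for none.
#' @param defaults,overrides Named lists layered under/over the file
#'   contents.
#' @return Named list.
#' @export
read_config <- function(path = NULL, defaults = list(),
                        overrides = list()) {
  cfg <- defaults
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      ln <- sub("=", " ", ln, fixed = TRUE)
      parts <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(parts) < 2L) {
        stop("malformed config line: '", ln, "'", call. = FALSE)
      }
      val <- paste(parts[-1], collapse = " ")
      num <- suppressWarnings(as.numeric(val))
      cfg[[parts[1]]] <- if (!is.na(num)) num else val
    }
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

## small polynomial rolling hash of a deparsed object, for run-log
## provenance (not cryptographic)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> decompose -> fit -> derive, writing a
#' terms file, a fit report, chi-squared profiles for requested parameters,
#' and a run log recording package version, seed, config hash and stage
#' timings. Deterministic: rerunning with the same configuration gives
#' byte-identical numeric outputs.
#'
#' @param config Named list. Either `manifest` (path to measured data) or
#'   `simulate = TRUE` with an `asaxs_config` under `sim_config`. Optional:
#'   `initial` ([biphasic_params()]; defaults to [default_truth()]),
#'   `comps` (defaults to compositions for the dataset's element),
#'   `fixed`, `profile_params` (character vector to chi2-map), `seed`.
#' @param out_dir Output directory.
#' @return List with the dataset, terms, fit, derived quantities and file
#'   paths (invisibly returns the same).
#' @export
run_pipeline <- function(config, out_dir) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- if (!is.null(config$seed)) config$seed else 1L
  ## --- load or simulate -------------------------------------------------
  dataset <- stage("input", {
    if (isTRUE(config$simulate)) {
      if (is.null(config$sim_config)) {
        stop("simulate = TRUE requires a 'sim_config'")
      }
      generate_asaxs(config$sim_config)
    } else {
      if (is.null(config$manifest)) {
        stop("config needs either 'manifest' or 'simulate = TRUE'")
      }
      read_energy_scan(config$manifest)
    }
  })
  tick("input")
  comps <- if (!is.null(config$comps)) config$comps else
    phase_compositions(dataset$resonant_element)
  ## --- decompose --------------------------------------------------------
  terms <- stage("decompose", decompose(dataset))
  terms_path <- file.path(out_dir, "terms.txt")
  write_terms(terms_path, terms)
  cs <- validate_cauchy_schwarz(terms, tolerance = 0.1)
  tick("decompose")
  ## --- fit --------------------------------------------------------------
  initial <- if (!is.null(config$initial)) config$initial else
    default_truth()
  fixed <- if (!is.null(config$fixed)) config$fixed else
    c("phase1_density", "phase1_volfrac", "phase2_density",
      "phase2_volfrac")
  fit <- stage("fit", fit_biphasic(terms, comps, initial, fixed = fixed))
  tick("fit")
  ## --- profiles ---------------------------------------------------------
  profiles <- list()
  for (pm in config$profile_params) {
    prof <- stage("chi2_map", chi2_map(fit, terms, pm))
    profiles[[pm]] <- prof
    utils::write.table(
      prof$profile, file.path(out_dir, paste0("profile_", pm, ".txt")),
      row.names = FALSE, quote = FALSE)
  }
  tick("profiles")
  ## --- derived quantities ----------------------------------------------
  derived <- stage("derive", list(
    ions_per_peptide = ions_per_peptide(fit),
    phase_metal_concentrations = phase_metal_concentrations(fit),
    guinier_radius = guinier_radius(fit$best_params)))
  ## --- report -----------------------------------------------------------
  report_path <- file.path(out_dir, "fit_report.txt")
  p <- fit$best_params
  xmodfit_names <- c(norm = "norm", phase1_density = "Phase1_Density",
                     phase1_volfrac = "Phase1_volFrac",
                     phase1_rmoles = "Phase1_rmoles",
                     phase2_density = "Phase2_Density",
                     phase2_volfrac = "Phase2_volFrac",
                     mean_radius = "Phase1_R", rsig = "Rsig")
  rpt <- c("# biphasic sphere fit report",
           "# Q in 1/A, energies in keV, intensities in 1/cm",
           sprintf("%s %.12g", xmodfit_names[.param_names],
                   unlist(p[.param_names])),
           sprintf("chi2 %.12g", fit$chi2),
           sprintf("dof %d", fit$dof),
           sprintf("chi2_per_dof %.12g", fit$chi2 / fit$dof),
           sprintf("ions_per_peptide %.12g", derived$ions_per_peptide),
           sprintf("phase1_metal_molar %.12g",
                   derived$phase_metal_concentrations$phase1),
           sprintf("phase2_metal_molar %.12g",
                   derived$phase_metal_concentrations$phase2),
           sprintf("guinier_radius_A %.12g", derived$guinier_radius),
           sprintf("cauchy_schwarz_violations %d", cs$n_violations))
  writeLines(rpt, report_path)
  ## --- log --------------------------------------------------------------
  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    sprintf("asaxsfit %s",
            as.character(utils::packageVersion("asaxsfit"))),
    sprintf("seed %d", as.integer(seed)),
    sprintf("config_hash %s", .config_hash(config)),
    sprintf("stage_seconds %s",
            paste(sprintf("%s=%.3f", names(timings), unlist(timings)),
                  collapse = " "))), log_path)
  invisible(list(dataset = dataset, terms = terms, fit = fit,
                 profiles = profiles, derived = derived,
                 cauchy_schwarz = cs,
                 paths = list(terms = terms_path, report = report_path,
                              log = log_path)))
}
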
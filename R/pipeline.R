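#' Run the full prediction pipeline
#'
#' Orchestrates the workflow end to end: obtain a feed profile (from a
#' profile CSV, a chromatogram CSV, or a seeded synthetic preset),
#' calibrate each membrane (from printed coefficients or from a
#' permeate/retentate chromatogram pair), sweep the prediction over a VRF
#' grid, and write the results: one sweep CSV and one calibration record
#' per membrane, a machine-readable summary CSV, and a human-readable
#' report. Report values are printed with the same formatter as the
#' summary CSV, so the two agree byte for byte. Given a fixed config and
#' seed the outputs are identical across runs.
#'
#' @param config A named list (or path to a YAML file holding one) with
#'   elements:
#'   \describe{
#'     \item{seed}{integer seed (default 1).}
#'     \item{column}{`slope`, `intercept` of the SEC column calibration
#'       (defaults to the built-in Superdex peptide calibration).}
#'     \item{profile}{one of `csv` (path to a `time_min,mw_gmol,conc_gL`
#'       profile), `chromatogram` (path to a chromatogram CSV), or
#'       `preset` (a [dh_preset()] name, with optional `noise_sd`).}
#'     \item{membranes}{named list; each entry either
#'       `list(slope =, intercept =)` or
#'       `list(permeate =, retentate =)` chromatogram CSV paths (optional
#'       `threshold`, `mw_window`).}
#'     \item{target}{`name`, `mw`, `initial_purity` (percent; filled from
#'       the preset truth when available).}
#'     \item{vrf}{VRFs to report on (default `c(1.1, 3, 5, 10)`).}
#'     \item{vrf_grid}{sweep grid (default 90 log-spaced points,
#'       1.1-10).}
#'   }
#' @param out_dir Output directory; created if needed.
#' @return An object of class `"uf_report"`: per-membrane calibrations,
#'   target retentions, apparent MWCOs, the report table and full sweeps,
#'   plus the rendered report text and file paths.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("stage 'config': input file not found: ", config, call. = FALSE)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  col_cfg <- config$column %||% list()
  column_cal <- column_calibration(col_cfg$slope %||% -0.082,
                                   col_cfg$intercept %||% 5.382)
  ref <- protein_reference()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need_file <- function(path, stage) {
    if (is.null(path) || !file.exists(path))
      stop(sprintf("stage '%s': input file not found: %s", stage,
                   path %||% "<missing>"), call. = FALSE)
    path
  }

  ## feed profile
  pr_cfg <- config$profile %||% stop("config lacks a `profile` entry",
                                     call. = FALSE)
  truth_purity <- NULL
  if (!is.null(pr_cfg$csv)) {
    d <- utils::read.csv(need_file(pr_cfg$csv, "profile"))
    profile <- hydrolysate_profile(d$mw_gmol, d$conc_gL, time = d$time_min,
                                   label = basename(pr_cfg$csv))
    profile_desc <- paste0("profile CSV '", pr_cfg$csv, "'")
  } else if (!is.null(pr_cfg$chromatogram)) {
    chrom <- read_chromatogram(need_file(pr_cfg$chromatogram, "profile"))
    profile <- absorbance_to_concentration(chrom, column_cal, ref,
                                           denoise = TRUE)
    profile_desc <- paste0("chromatogram CSV '", pr_cfg$chromatogram, "'")
  } else if (!is.null(pr_cfg$preset)) {
    spec <- dh_preset(pr_cfg$preset, seed = seed,
                      noise_sd = pr_cfg$noise_sd %||% 0)
    gen <- generate_hydrolysate(spec, column_cal, ref)
    profile <- absorbance_to_concentration(gen$chromatogram, column_cal, ref,
                                           denoise = TRUE)
    truth_purity <- truth_initial_purity(gen$truth)
    profile_desc <- paste0("synthetic preset '", pr_cfg$preset, "'")
  } else {
    stop("stage 'profile': supply `csv`, `chromatogram` or `preset`",
         call. = FALSE)
  }

  tg_cfg <- config$target %||% list()
  target <- target_peptide(
    name = tg_cfg$name %||% "neokyotorphin",
    mw = tg_cfg$mw %||% 653,
    initial_purity = tg_cfg$initial_purity %||% truth_purity)

  ## membranes
  mem_cfg <- config$membranes %||% stop("config lacks a `membranes` entry",
                                        call. = FALSE)
  if (is.null(names(mem_cfg)) || any(!nzchar(names(mem_cfg))))
    stop("`membranes` entries must be named", call. = FALSE)
  membranes <- lapply(names(mem_cfg), function(nm) {
    m <- mem_cfg[[nm]]
    if (!is.null(m$slope)) {
      membrane_calibration(m$slope, m$intercept,
                           mwco_nominal = m$mwco_nominal)
    } else {
      perm <- read_chromatogram(need_file(m$permeate, "calibrate-membrane"))
      ret <- read_chromatogram(need_file(m$retentate, "calibrate-membrane"))
      series <- pointwise_retention(perm, ret, column_cal,
                                    threshold = m$threshold %||% 0.02)
      fit_membrane_calibration(series,
                               mw_window = m$mw_window %||% column_cal$mw_range,
                               mwco_nominal = m$mwco_nominal)
    }
  })
  names(membranes) <- names(mem_cfg)

  report_vrf <- as.numeric(config$vrf %||% c(1.1, 3, 5, 10))
  grid <- as.numeric(config$vrf_grid %||% 10^seq(log10(1.1), 1,
                                                 length.out = 90L))

  results <- lapply(names(membranes), function(nm) {
    cal <- membranes[[nm]]
    sweep <- vrf_sweep(profile, cal, target, vrf = grid)
    at <- vrf_sweep(profile, cal, target, vrf = sort(report_vrf))
    mwco <- if (cal$slope > 0 && cal$intercept < 0.9)
      apparent_mwco(cal) else NA_real_
    sweep_path <- file.path(out_dir, paste0(nm, "_sweep.csv"))
    utils::write.csv(as.data.frame(sweep), sweep_path, row.names = FALSE)
    cal_path <- file.path(out_dir, paste0(nm, "_calibration.txt"))
    writeLines(c(
      paste0("membrane: ", nm),
      paste0("slope: ", fmt_num(cal$slope)),
      paste0("intercept: ", fmt_num(cal$intercept)),
      paste0("r_squared: ", fmt_num(cal$r_squared)),
      paste0("apparent_mwco_gmol: ", fmt_num(mwco)),
      paste0("fit_mw_window: ",
             if (is.null(cal$fit_mw_window)) "NA"
             else paste(fmt_num(cal$fit_mw_window), collapse = " "))),
      cal_path)
    list(name = nm, calibration = cal,
         retention_target = retention_at(cal, target$mw),
         apparent_mwco = mwco, table = at, sweep = sweep,
         files = c(sweep = sweep_path, calibration = cal_path))
  })
  names(results) <- names(membranes)

  ## machine-readable summary (formatted with the same fmt_num as the report)
  summary_rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(membrane = r$name,
               vrf = fmt_num(r$table$vrf),
               retention_target = fmt_num(r$retention_target),
               apparent_mwco_gmol = fmt_num(r$apparent_mwco),
               yield = fmt_num(r$table$yield),
               enrichment = fmt_num(r$table$enrichment),
               purity_pct = fmt_num(r$table$purity_pct),
               sum_cp_gL = fmt_num(r$table$sum_cp_gL))
  }))
  summary_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(summary_rows, summary_path, row.names = FALSE,
                   quote = FALSE)

  ## human-readable report from the same formatted values
  lines <- c("UF fractionation prediction report",
             paste0("seed: ", seed),
             paste0("feed: ", profile_desc,
                    sprintf(" (total %s g/L)", fmt_num(profile$total_concentration))),
             paste0("target: ", target$name, " (", fmt_num(target$mw), " g/mol",
                    if (!is.null(target$initial_purity))
                      paste0(", initial purity ", fmt_num(target$initial_purity), " %")
                    else "", ")"),
             "")
  for (r in results) {
    lines <- c(lines,
      paste0("membrane '", r$name, "'"),
      paste0("  calibration: R = ", fmt_num(r$calibration$slope),
             " * log10(MW) + (", fmt_num(r$calibration$intercept), ")"),
      paste0("  retention of target: ", fmt_num(r$retention_target)),
      paste0("  apparent MWCO (90% retention): ",
             fmt_num(r$apparent_mwco), " g/mol"),
      vapply(seq_len(nrow(r$table)), function(i) {
        paste0("  VRF ", fmt_num(r$table$vrf[i]),
               ": yield ", fmt_num(r$table$yield[i]),
               ", enrichment ", fmt_num(r$table$enrichment[i]),
               ", purity ", fmt_num(r$table$purity_pct[i]), " %",
               ", sum Cp ", fmt_num(r$table$sum_cp_gL[i]), " g/L")
      }, character(1L)),
      "")
  }
  report_path <- file.path(out_dir, "report.txt")
  writeLines(lines, report_path)

  structure(list(target = target, profile = profile, column_cal = column_cal,
                 membranes = results, report_text = lines,
                 files = c(summary = summary_path, report = report_path)),
            class = "uf_report")
}

#' @export
print.uf_report <- function(x, ...) {
  cat(x$report_text, sep = "\n")
  invisible(x)
}
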
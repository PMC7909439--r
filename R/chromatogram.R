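#' Size-exclusion chromatogram
#'
#' A UV absorbance trace recorded on a size-exclusion column: elution time
#' (minutes, strictly increasing) versus absorbance (AU) at a stated
#' wavelength, together with the optical path length of the detection cell.
#'
#' @param time Elution times in minutes; strictly increasing.
#' @param absorbance Absorbances in AU at `wavelength`; finite, same length
#'   as `time`.
#' @param wavelength Detection wavelength in nm. Peptide-bond detection is
#'   conventionally done at 214 nm (the default).
#' @param path_length Optical path of the detection cell in cm; must be
#'   positive.
#' @param label Free-text label carried through plots and reports.
#' @return An object of class `"chromatogram"`.
#' @seealso [read_chromatogram()], [absorbance_to_concentration()]
#' @examples
#' chromatogram(time = 0:2, absorbance = c(0, 0.5, 0))
#' @export
chromatogram <- function(time, absorbance, wavelength = 214, path_length = 1,
                         label = "") {
  time <- as.numeric(time)
  absorbance <- as.numeric(absorbance)
  if (length(time) != length(absorbance))
    stop("`time` and `absorbance` must have the same length", call. = FALSE)
  if (length(time) < 1L)
    stop("a chromatogram needs at least one point", call. = FALSE)
  if (any(!is.finite(time)))
    stop("elution times must be finite", call. = FALSE)
  if (any(!is.finite(absorbance)))
    stop("absorbance values must be finite", call. = FALSE)
  bad <- which(diff(time) <= 0)
  if (length(bad))
    stop(sprintf(
      "elution time must be strictly increasing; first violation at index %d",
      bad[1L] + 1L), call. = FALSE)
  if (!is.numeric(path_length) || length(path_length) != 1L || path_length <= 0)
    stop("`path_length` must be a positive scalar (cm)", call. = FALSE)
  structure(
    list(time = time, absorbance = absorbance,
         wavelength = as.numeric(wavelength),
         path_length = as.numeric(path_length),
         label = as.character(label)[1L]),
    class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("Size-exclusion chromatogram",
      if (nzchar(x$label)) paste0("'", x$label, "'") else "", "\n")
  cat(sprintf("  %d points, %.6g-%.6g min, %g nm, %g cm path\n",
              length(x$time), min(x$time), max(x$time),
              x$wavelength, x$path_length))
  invisible(x)
}

#' @export
as.data.frame.chromatogram <- function(x, ...) {
  data.frame(time_min = x$time, absorbance_au = x$absorbance)
}

#' @export
plot.chromatogram <- function(x, ...) {
  graphics::plot(x$time, x$absorbance, type = "l",
                 xlab = "elution time (min)",
                 ylab = sprintf("absorbance at %g nm (AU)", x$wavelength),
                 main = x$label, ...)
  invisible(x)
}

#' Read a chromatogram from a delimited text file
#'
#' Expects a two-column file (elution time in minutes, absorbance in AU),
#' optionally with a header line. The delimiter, decimal mark and header
#' convention form the dialect; the default is comma / point / header-on,
#' matching the files written by [write_chromatogram()].
#'
#' @param path Path to the file.
#' @param sep Field delimiter.
#' @param dec Decimal mark.
#' @param header Logical; does the file start with a header line?
#' @param wavelength,path_length,label Passed to [chromatogram()]; `label`
#'   defaults to the file name.
#' @return A validated [chromatogram()].
#' @export
read_chromatogram <- function(path, sep = ",", dec = ".", header = TRUE,
                              wavelength = 214, path_length = 1,
                              label = basename(path)) {
  if (!file.exists(path))
    stop("chromatogram file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expected two columns (time, absorbance) in ", path, call. = FALSE)
  parse_col <- function(v, what) {
    if (dec != ".") v <- gsub(dec, ".", v, fixed = TRUE)
    x <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(x))
    if (length(bad))
      stop(sprintf("could not parse '%s' as a number (%s column, line %d of %s)",
                   v[bad[1L]], what, bad[1L] + as.integer(header),
                   basename(path)), call. = FALSE)
    x
  }
  chromatogram(parse_col(raw[[1L]], "time"),
               parse_col(raw[[2L]], "absorbance"),
               wavelength = wavelength, path_length = path_length,
               label = label)
}

#' Write a chromatogram to CSV
#'
#' Columns `time_min,absorbance_au`, written with enough digits that
#' [read_chromatogram()] reproduces the values to better than 1e-12
#' relative.
#'
#' @param x A [chromatogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(x, path) {
  stopifnot(inherits(x, "chromatogram"))
  df <- data.frame(time_min = sprintf("%.15g", x$time),
                   absorbance_au = sprintf("%.15g", x$absorbance))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Size-exclusion column calibration
#'
#' Linear map between elution time and log10 molar mass,
#' `log10(MW) = slope * time + intercept`. The default coefficients are for
#' a Superdex peptide column calibrated with 45 synthetic peptides spanning
#' 220-1890 g/mol: `log10(MW) = -0.082 * Tr + 5.382`.
#'
#' @param slope Per-minute slope of log10(MW) versus elution time; non-zero
#'   (negative for size exclusion: larger solutes elute earlier).
#' @param intercept Dimensionless intercept.
#' @param mw_range Validity window in g/mol (the molar-mass span of the
#'   calibration standards). Values outside are still converted but
#'   flagged.
#' @return An object of class `"column_calibration"`.
#' @export
column_calibration <- function(slope = -0.082, intercept = 5.382,
                               mw_range = c(220, 1890)) {
  if (!is.numeric(slope) || length(slope) != 1L || slope == 0)
    stop("`slope` must be a non-zero scalar", call. = FALSE)
  mw_range <- as.numeric(mw_range)
  if (length(mw_range) != 2L || !all(is.finite(mw_range)) ||
      mw_range[1L] >= mw_range[2L] || mw_range[1L] <= 0)
    stop("`mw_range` must be positive with min < max", call. = FALSE)
  structure(list(slope = as.numeric(slope),
                 intercept = as.numeric(intercept),
                 mw_range = mw_range),
            class = "column_calibration")
}

#' @export
print.column_calibration <- function(x, ...) {
  cat(sprintf("SEC column calibration: log10(MW) = %g * Tr %+g  (valid %g-%g g/mol)\n",
              x$slope, x$intercept, x$mw_range[1L], x$mw_range[2L]))
  invisible(x)
}

#' Molar mass at an elution time (and the inverse)
#'
#' `mw_at_time()` evaluates `10^(slope * tr + intercept)`; `time_at_mw()`
#' inverts it. Results outside the calibration's validity window are
#' returned (extrapolation is permitted) but flagged in the
#' `"out_of_range"` attribute of the result.
#'
#' @param cal A [column_calibration()].
#' @param tr Elution times in minutes (finite).
#' @param mw Molar masses in g/mol (positive).
#' @return `mw_at_time()`: molar masses in g/mol with a logical
#'   `"out_of_range"` attribute; `time_at_mw()`: elution times in minutes.
#' @export
mw_at_time <- function(cal, tr) {
  stopifnot(inherits(cal, "column_calibration"))
  if (any(!is.finite(tr))) stop("`tr` must be finite", call. = FALSE)
  mw <- 10^(cal$slope * tr + cal$intercept)
  attr(mw, "out_of_range") <- mw < cal$mw_range[1L] | mw > cal$mw_range[2L]
  mw
}

#' @rdname mw_at_time
#' @export
time_at_mw <- function(cal, mw) {
  stopifnot(inherits(cal, "column_calibration"))
  if (any(!is.finite(mw) | mw <= 0)) stop("`mw` must be positive", call. = FALSE)
  (log10(mw) - cal$intercept) / cal$slope
}

#' Per-residue UV reference constants of the hydrolysed protein
#'
#' The mean molar mass per amino-acid residue and the mean molar extinction
#' coefficient per residue at 214 nm, computed from the protein's primary
#' sequence. The defaults are the bovine hemoglobin values, 115 g/mol and
#' 987 L/mol/cm.
#'
#' @param mean_residue_mass Mean residue molar mass in g/mol; positive.
#' @param mean_residue_extinction Mean residue molar extinction coefficient
#'   at 214 nm in L/mol/cm; positive.
#' @param name Protein name.
#' @return An object of class `"protein_reference"`.
#' @export
protein_reference <- function(mean_residue_mass = 115,
                              mean_residue_extinction = 987,
                              name = "bovine hemoglobin") {
  if (mean_residue_mass <= 0 || mean_residue_extinction <= 0)
    stop("reference constants must be positive", call. = FALSE)
  structure(list(mean_residue_mass = as.numeric(mean_residue_mass),
                 mean_residue_extinction = as.numeric(mean_residue_extinction),
                 name = as.character(name)),
            class = "protein_reference")
}

#' Hydrolysate molar-mass/concentration profile
#'
#' Per-point (molar mass, mass concentration) representation of a
#' hydrolysate. When a `time` grid is supplied the concentrations are a
#' density over elution time (g/L/min) and the total concentration is their
#' trapezoidal integral; without a grid the concentrations are discrete
#' point masses (g/L) and the total is their sum. The discrete form is
#' convenient for small, exactly-known species mixtures.
#'
#' @param mw Molar masses in g/mol; positive.
#' @param concentration Non-negative concentrations (density over `time`,
#'   or point masses when `time` is `NULL`).
#' @param time Optional elution-time grid (minutes, strictly increasing).
#' @param target Optional [target_peptide()] annotation.
#' @param label Free text.
#' @return An object of class `"hydrolysate_profile"` with fields `mw`,
#'   `concentration`, `time`, `total_concentration`, `target`.
#' @export
hydrolysate_profile <- function(mw, concentration, time = NULL, target = NULL,
                                label = "") {
  mw <- as.numeric(mw)
  concentration <- as.numeric(concentration)
  if (length(mw) != length(concentration))
    stop("`mw` and `concentration` must have the same length", call. = FALSE)
  if (length(mw) < 1L) stop("empty profile", call. = FALSE)
  if (any(!is.finite(mw) | mw <= 0))
    stop("molar masses must be positive and finite", call. = FALSE)
  if (any(!is.finite(concentration) | concentration < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  if (!is.null(time)) {
    time <- as.numeric(time)
    if (length(time) != length(mw))
      stop("`time` must match the profile length", call. = FALSE)
    if (any(diff(time) <= 0))
      stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(target)) stopifnot(inherits(target, "target_peptide"))
  total <- sum(concentration * if (is.null(time)) 1 else trapezoid_weights(time))
  structure(list(mw = mw, concentration = concentration, time = time,
                 total_concentration = total, target = target,
                 label = as.character(label)[1L]),
            class = "hydrolysate_profile")
}

#' @export
print.hydrolysate_profile <- function(x, ...) {
  cat("Hydrolysate profile",
      if (nzchar(x$label)) paste0("'", x$label, "'") else "", "\n")
  cat(sprintf("  %d points, MW %.4g-%.4g g/mol, total %.4g g/L%s\n",
              length(x$mw), min(x$mw), max(x$mw), x$total_concentration,
              if (is.null(x$time)) " (discrete species)" else ""))
  if (!is.null(x$target))
    cat(sprintf("  target: %s (%g g/mol)\n", x$target$name, x$target$mw))
  invisible(x)
}

#' @export
as.data.frame.hydrolysate_profile <- function(x, ...) {
  d <- data.frame(mw_gmol = x$mw, conc_gL = x$concentration)
  if (!is.null(x$time)) d <- cbind(data.frame(time_min = x$time), d)
  d
}

#' Convert a chromatogram into a concentration profile
#'
#' Applies the per-residue Beer-Lambert conversion
#' `C_x = A_x * MWaa / (epsilon_aa * l) * normalization`
#' pointwise, and maps each elution time to a molar mass through the column
#' calibration. With the default `normalization = 1` the result is a
#' concentration density over elution time whose integral is the total
#' peptide concentration on the chromatogram's own scale; a different
#' injection/elution-volume convention is carried explicitly through
#' `normalization`. All quantities derived as ratios (enrichment, purity,
#' yield) are independent of this factor.
#'
#' @param chrom A [chromatogram()].
#' @param column_cal A [column_calibration()] supplying the molar masses.
#' @param ref A [protein_reference()] with the per-residue constants.
#' @param baseline_window Optional time window `c(t1, t2)` (minutes); the
#'   minimum absorbance inside it is subtracted as a constant baseline.
#' @param normalization Dimensionless factor linking chromatogram area to
#'   sample concentration (injection volume / flow-rate convention).
#' @param target Optional [target_peptide()] annotation, passed through.
#' @param denoise Logical. When `TRUE` the trace is smoothed with a short
#'   running mean (`smooth_window` points) and points below a noise floor
#'   of three post-smoothing noise standard deviations are set to zero.
#'   The noise level is estimated robustly from the median absolute
#'   successive difference of the raw trace. Without this, zero-mean
#'   detector noise rectified by the clip-at-zero rule adds spurious mass
#'   over the baseline, which biases integral quantities such as the
#'   enrichment denominator. Off by default so that clean traces convert
#'   exactly pointwise.
#' @param smooth_window Running-mean width in points (odd; used when
#'   `denoise = TRUE`).
#' @return A [hydrolysate_profile()] on the chromatogram's time grid.
#'   Negative absorbances (after baseline subtraction) are clipped to zero
#'   with a warning giving the count.
#' @export
absorbance_to_concentration <- function(chrom, column_cal,
                                        ref = protein_reference(),
                                        baseline_window = NULL,
                                        normalization = 1,
                                        target = NULL,
                                        denoise = FALSE,
                                        smooth_window = 9L) {
  stopifnot(inherits(chrom, "chromatogram"),
            inherits(column_cal, "column_calibration"),
            inherits(ref, "protein_reference"))
  a <- chrom$absorbance
  if (isTRUE(denoise) && length(a) > smooth_window) {
    sigma <- stats::median(abs(diff(a))) / (sqrt(2) * 0.6745)
    sm <- stats::filter(a, rep(1 / smooth_window, smooth_window), sides = 2)
    edge <- is.na(sm)
    sm[edge] <- a[edge]
    a <- as.numeric(sm)
    a[a < 3 * sigma / sqrt(smooth_window)] <- 0
  }
  if (!is.null(baseline_window)) {
    inside <- chrom$time >= baseline_window[1L] & chrom$time <= baseline_window[2L]
    if (!any(inside))
      stop("`baseline_window` contains no chromatogram points", call. = FALSE)
    a <- a - min(a[inside])
  }
  neg <- a < 0
  if (any(neg)) {
    warning(sprintf("%d negative absorbance value(s) clipped to 0", sum(neg)),
            call. = FALSE)
    a[neg] <- 0
  }
  conc <- a * ref$mean_residue_mass /
    (ref$mean_residue_extinction * chrom$path_length) * normalization
  mw <- mw_at_time(column_cal, chrom$time)
  out_of_range <- attr(mw, "out_of_range")
  prof <- hydrolysate_profile(as.numeric(mw), conc, time = chrom$time,
                              target = target, label = chrom$label)
  attr(prof, "n_out_of_range") <- sum(out_of_range)
  prof
}

#' Write a profile to CSV (`time_min,mw_gmol,conc_gL`)
#' @param x A [hydrolysate_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  stopifnot(inherits(x, "hydrolysate_profile"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Per-point masses (g/L) of a profile: trapezoid-weighted density on a
# grid, or the concentrations themselves for a discrete profile.
point_masses <- function(profile) {
  stopifnot(inherits(profile, "hydrolysate_profile"))
  if (is.null(profile$time)) profile$concentration
  else profile$concentration * trapezoid_weights(profile$time)
}

#' Cumulative molar-mass distribution (in mass)
#'
#' Sorts the profile's point masses by molar mass and accumulates them into
#' the molar-weight cumulative frequency in mass: a non-decreasing curve
#' from 0 to 1 over increasing MW.
#'
#' @param profile A [hydrolysate_profile()] with positive total mass.
#' @return A data frame of class `"mw_distribution"` with columns
#'   `mw_gmol` and `cum_mass_fraction`.
#' @export
cumulative_mass_distribution <- function(profile) {
  m <- point_masses(profile)
  total <- sum(m)
  if (total <= 0) stop("profile has zero total mass", call. = FALSE)
  o <- order(profile$mw)
  out <- data.frame(mw_gmol = profile$mw[o],
                    cum_mass_fraction = cumsum(m[o]) / total)
  class(out) <- c("mw_distribution", "data.frame")
  out
}

#' @export
plot.mw_distribution <- function(x, ...) {
  graphics::plot(x$mw_gmol, x$cum_mass_fraction, type = "l", log = "x",
                 xlab = "molar mass (g/mol)",
                 ylab = "cumulative mass fraction", ...)
  invisible(x)
}

#' Median molar mass and mass fraction below a threshold
#'
#' `median_mw()` returns the molar mass at cumulative mass fraction 0.5,
#' linearly interpolated between grid points. `fraction_below()` returns
#' the mass fraction of peptides with molar mass at or below `mw_threshold`.
#'
#' @param profile A [hydrolysate_profile()] with positive total mass.
#' @param mw_threshold Molar-mass threshold in g/mol.
#' @return A scalar (g/mol for `median_mw()`, a fraction in `[0, 1]` for
#'   `fraction_below()`).
#' @export
median_mw <- function(profile) {
  m <- point_masses(profile)
  total <- sum(m)
  if (total <= 0) stop("profile has zero total mass", call. = FALSE)
  o <- order(profile$mw)
  mw <- profile$mw[o]
  m <- m[o]
  if (length(mw) == 1L) return(mw)
  # midpoint convention: each point mass sits at the centre of its own
  # cumulative increment, so a symmetric mixture returns its centre
  mid <- (cumsum(m) - m / 2) / total
  keep <- c(TRUE, diff(mid) > 0)
  mw <- mw[keep]
  mid <- mid[keep]
  if (mid[1L] >= 0.5) return(mw[1L])
  if (mid[length(mid)] <= 0.5) return(mw[length(mw)])
  stats::approx(mid, mw, xout = 0.5, ties = "ordered")$y
}

#' @rdname median_mw
#' @export
fraction_below <- function(profile, mw_threshold) {
  m <- point_masses(profile)
  total <- sum(m)
  if (total <= 0) stop("profile has zero total mass", call. = FALSE)
  sum(m[profile$mw <= mw_threshold]) / total
}
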
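#' @include core-model.R
NULL

# full-precision numeric formatting for lossless CSV round trips
.fmtNum <- function(x) formatC(x, digits = 17, format = "g")

.sidecarPath <- function(csvPath) sub("\\.csv$", ".json", csvPath)

#' Read a force-clamp trace from CSV plus JSON sidecar
#'
#' The CSV dialect has columns `time_s,extension_nm_per_bp`; the sidecar
#' (same path with `.json` extension) carries at least `force_pN` and
#' `concentration_nM`, plus optional `temperature_K`, `bp_count` and
#' `label`. Validation errors name the offending file and line.
#'
#' @param csvPath path to the trace CSV.
#' @return a [ForceClampTrace-class]; sidecar fields are kept in `meta`.
#' @export
readTrace <- function(csvPath) {
  if (!file.exists(csvPath))
    stop("trace file not found: ", csvPath, call. = FALSE)
  side <- .sidecarPath(csvPath)
  if (!file.exists(side))
    stop("missing sidecar: expected metadata file ", side, call. = FALSE)
  meta <- jsonlite::fromJSON(side)
  for (fld in c("force_pN", "concentration_nM"))
    if (is.null(meta[[fld]]))
      stop("sidecar ", side, " lacks required field ", fld, call. = FALSE)
  df <- utils::read.csv(csvPath)
  if (!all(c("time_s", "extension_nm_per_bp") %in% names(df)))
    stop(csvPath, ": expected columns time_s,extension_nm_per_bp",
         call. = FALSE)
  if (anyNA(df$time_s) || anyNA(df$extension_nm_per_bp))
    stop(csvPath, ": non-numeric values at line(s) ",
         paste(which(is.na(df$time_s) | is.na(df$extension_nm_per_bp)) + 1L,
               collapse = ", "), call. = FALSE)
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop(csvPath, ": time not strictly increasing at line(s) ",
         paste(bad + 2L, collapse = ", "), call. = FALSE)
  ForceClampTrace(df$time_s, df$extension_nm_per_bp,
                  force = meta$force_pN,
                  concentration = meta$concentration_nM,
                  label = if (!is.null(meta$label)) meta$label else
                    basename(csvPath),
                  meta = meta)
}

#' Write a force-clamp trace as CSV plus JSON sidecar
#'
#' Values are written with 17 significant digits so that
#' `readTrace(writeTrace(...))` is an identity to better than 1e-12 and
#' the sidecar metadata round-trips verbatim.
#'
#' @param trace a [ForceClampTrace-class].
#' @param csvPath destination CSV path; the sidecar goes next to it.
#' @return `csvPath`, invisibly.
#' @export
writeTrace <- function(trace, csvPath) {
  stopifnot(is(trace, "ForceClampTrace"))
  df <- data.frame(time_s = .fmtNum(trace@times),
                   extension_nm_per_bp = .fmtNum(trace@extensions))
  utils::write.csv(df, csvPath, row.names = FALSE, quote = FALSE)
  meta <- trace@meta
  meta$force_pN <- trace@force
  meta$concentration_nM <- trace@concentration
  meta$label <- trace@label
  jsonlite::write_json(meta, .sidecarPath(csvPath), auto_unbox = TRUE,
                       digits = NA)
  invisible(csvPath)
}

#' Read all traces in a directory
#'
#' @param dir directory containing `*.csv` traces with JSON sidecars.
#' @return list of [ForceClampTrace-class].
#' @export
readTraceDir <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[file.exists(.sidecarPath(files))] # traces have sidecars
  if (!length(files))
    stop("no trace CSV files (with JSON sidecars) found in ", dir,
         call. = FALSE)
  lapply(sort(files), readTrace)
}

#' Read an equilibrium titration table
#'
#' CSV dialect `force_pN,concentration_nM,L_eq_nm_per_bp[,sd]`.
#'
#' @param path CSV path.
#' @return data.frame with columns force, concentration, Leq and
#'   optionally sd.
#' @export
readTitration <- function(path) {
  if (!file.exists(path)) stop("titration file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("force_pN", "concentration_nM", "L_eq_nm_per_bp")
  if (!all(need %in% names(df)))
    stop(path, ": expected columns ", paste(need, collapse = ","),
         call. = FALSE)
  out <- data.frame(force = df$force_pN,
                    concentration = df$concentration_nM,
                    Leq = df$L_eq_nm_per_bp)
  if (!is.null(df$sd)) out$sd <- df$sd
  out
}

.bellToList <- function(b) {
  if (is.null(b)) return(NULL)
  list(quantity = b@quantity, zeroForceValue = b@zeroForceValue,
       distance = b@distance, se = as.list(b@se), nPoints = b@nPoints)
}

#' Serialise an analysis report to JSON
#'
#' Writes every fitted quantity with its route provenance, the stage
#' warnings and the seed as a versioned JSON document.
#'
#' @param report an [AnalysisReport-class].
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "AnalysisReport"))
  iso <- lapply(report@isotherms, function(f) list(
    force = f@force, Kd = f@Kd, n = f@n, Lsat = f@Lsat,
    se = as.list(f@se), nPoints = f@nPoints,
    nonIdentifiable = f@nonIdentifiable))
  assoc <- lapply(report@associations, function(a) list(
    force = a@force, kA = a@slope, intercept = a@intercept,
    se = as.list(a@se), interceptZero = a@interceptZero))
  th <- report@thermo
  out <- list(
    schema = "threadclamp-report/1",
    seed = report@config@seed,
    relaxation = report@relaxation,
    equilibrium = report@equilibrium,
    saturation = report@satTable,
    satWLC = if (!is.null(report@satWLC)) list(
      persistenceLength = report@satWLC@persistenceLength,
      stretchModulus = report@satWLC@stretchModulus,
      contourPerBp = report@satWLC@contourPerBp,
      se = as.list(report@satWLC@se)) else NULL,
    isotherms = iso,
    rates = report@rates,
    associations = assoc,
    bell = list(Kd = .bellToList(report@kdBell),
                k_on = .bellToList(report@onBell),
                k_off = .bellToList(report@offBell),
                k_a = .bellToList(report@kaBell)),
    siteSize = if (!is.null(report@siteSize)) list(
      perForce = report@siteSize@perForce,
      mean = report@siteSize@mean, se = report@siteSize@se) else NULL,
    thermodynamics = if (!is.null(th)) list(
      deltaXRoutes = as.list(th@deltaXRoutes),
      routesAgree = th@routesAgree,
      gThreadKT = th@gThreadKT, gThreadKcal = th@gThreadKcal,
      kDif = th@kDif, kA0 = th@kA0,
      halfLifeZeroForce_s = th@halfLifeZeroForce) else NULL,
    warnings = report@warnings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
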
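# Physiological parameter set of the mechanistic host model.

PARAM_NAMES <- c("DV0", "DV1", "DV2", "DV3", "SM0", "SM1", "SM2", "SM3",
                 "TTCS", "THCS", "TTHS", "THHS", "SMDS", "HDS", "SMWS", "HWS")

#' Physiological parameters of the ecoclimatic engine
#'
#' The 16 thresholds and rates of the weekly growth/stress model:
#' temperature thresholds `DV0 <= DV1 <= DV2 <= DV3` (degC) bounding the
#' trapezoidal temperature index, soil-moisture thresholds
#' `SM0 <= SM1 <= SM2 <= SM3` (fraction of bucket capacity) bounding the
#' moisture index, and threshold/rate pairs for cold (`TTCS`/`THCS`), heat
#' (`TTHS`/`THHS`), dry (`SMDS`/`HDS`) and wet (`SMWS`/`HWS`) stress. Rates
#' are per week; cold and dry rates are conventionally printed with a
#' negative sign and are used by magnitude. Defaults are the fitted
#' *Cupressus* values.
#'
#' @param DV0,DV1,DV2,DV3 temperature threshold, lower optimum, upper
#'   optimum, upper threshold (degC).
#' @param SM0,SM1,SM2,SM3 soil-moisture analogues (dimensionless).
#' @param TTCS,THCS cold-stress temperature threshold (degC) and rate.
#' @param TTHS,THHS heat-stress threshold (degC) and rate.
#' @param SMDS,HDS dry-stress moisture threshold and rate.
#' @param SMWS,HWS wet-stress moisture threshold and rate.
#' @return an object of class `climex_params` (named numeric vector).
#' @export
climex_params <- function(DV0 = -15, DV1 = 13.6, DV2 = 20.4, DV3 = 45,
                          SM0 = 0.05, SM1 = 0.5, SM2 = 0.9, SM3 = 1.5,
                          TTCS = -15, THCS = -0.125, TTHS = 45, THHS = 0.015,
                          SMDS = 0.05, HDS = -0.005, SMWS = 1.5, HWS = 0.012) {
  p <- c(DV0 = DV0, DV1 = DV1, DV2 = DV2, DV3 = DV3,
         SM0 = SM0, SM1 = SM1, SM2 = SM2, SM3 = SM3,
         TTCS = TTCS, THCS = THCS, TTHS = TTHS, THHS = THHS,
         SMDS = SMDS, HDS = HDS, SMWS = SMWS, HWS = HWS)
  if (!all(is.finite(p))) stop("all parameters must be finite")
  if (is.unsorted(p[c("DV0", "DV1", "DV2", "DV3")])) {
    stop("temperature thresholds must satisfy DV0 <= DV1 <= DV2 <= DV3")
  }
  if (is.unsorted(p[c("SM0", "SM1", "SM2", "SM3")])) {
    stop("soil-moisture thresholds must satisfy SM0 <= SM1 <= SM2 <= SM3")
  }
  structure(p, class = "climex_params")
}

#' @export
print.climex_params <- function(x, ...) {
  cat("Ecoclimatic engine parameters:\n")
  print(unclass(x))
  invisible(x)
}

#' Read engine parameters from a key=value config file
#'
#' One `NAME=value` pair per line; `#` starts a comment. Keys are the
#' standard parameter symbols; missing keys take the default values.
#'
#' @param path config file path.
#' @return a [climex_params()].
#' @export
read_climex_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  unknown <- setdiff(keys, PARAM_NAMES)
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  do.call(climex_params, as.list(stats::setNames(vals, keys)))
}

#' Write engine parameters to a key=value config file
#'
#' @param p a [climex_params()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_climex_params <- function(p, path) {
  stopifnot(inherits(p, "climex_params"))
  writeLines(sprintf("%s=%.10g", names(p), as.numeric(p)), path)
  invisible(path)
}
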
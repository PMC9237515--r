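# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# 16-bit intensity ceiling of the imaging system
SATURATION <- 65535L

#' @noRd
clip16 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > SATURATION] <- SATURATION
  storage.mode(x) <- "integer"
  x
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical subtype vocabulary (fibroblast-free mammary marker patterns)
SUBTYPE_LEVELS <- c("P5", "P6", "P7", "P8", "UNASSIGNED")

# Marker channels: protein name -> default imaging channel
DEFAULT_MARKER_CHANNELS <- c(Epcam = "CY5", Cd49f = "FITC", `Sca-1` = "TRED")
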
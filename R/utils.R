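# Shared constants and small helpers.

#' Canonical timepoint ordering
#'
#' Samples are taken prepregnancy (`pre`), during the three trimesters
#' (`T1`--`T3`) and postpartum (`post`). All longitudinal logic orders
#' timepoints this way.
#'
#' @return Character vector of the five timepoint labels, in order.
#' @export
timepoint_levels <- function() c("pre", "T1", "T2", "T3", "post")

#' Canonical cytokine panel
#'
#' The twelve serum cytokines measured by ELISA, in fixed order. Column names
#' use syntactic forms (`IL4` for IL-4, `TNFa` for TNF-alpha, `IFNg` for
#' IFN-gamma).
#'
#' @return Character vector of the twelve cytokine column names.
#' @export
cytokine_names <- function() {
  c("IL4", "IL5", "IL6", "IL8", "IL9", "IL10",
    "IL12", "IL15", "IL17", "IL21", "TNFa", "IFNg")
}

group_levels <- function() c("CD", "UC", "IBDU", "control")

#' Round half away from zero
#'
#' Base R rounds half to even; cohort tables use conventional half-up
#' rounding (2.5 -> 2.5 at one decimal means 80.45 -> 80.5).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a 31-bit child seed from a master seed and a stage label, so stages
# can be rerun independently yet reproducibly.
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(paste0(label, ":", seed))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647L
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_pb <- function(...) stop(..., call. = FALSE)
warn_pb <- function(...) warning(..., call. = FALSE)
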
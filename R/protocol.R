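#' Multi-stage experimental protocol
#'
#' An ordered table of stages, each with a name, a duration in hours and
#' the set of external inputs switched on.  The canonical three-stage
#' conversion protocol is: fibroblast (72 h, no inputs; a stability
#' window), REST knockdown (72 h, `RESTi` on), conversion (default 504 h =
#' 21 days, `RESTi` and `vAscl1` on).
#'
#' @param stages data.frame with columns `name`, `duration` (hours) and a
#'   list-column `inputs` of character vectors.
#' @return object of class `grn_protocol`.
#' @export
grn_protocol <- function(stages) {
  stopifnot(is.data.frame(stages),
            all(c("name", "duration", "inputs") %in% names(stages)))
  if (any(stages$duration < 0)) stop("stage durations must be >= 0")
  if (anyDuplicated(stages$name)) stop("stage names must be unique")
  structure(stages, class = c("grn_protocol", "data.frame"))
}

#' @rdname grn_protocol
#' @param conversion_hours duration of the conversion stage (504 h covers
#'   the full 21-day observation window; fitting uses 120 h = 5 days).
#' @param fibroblast_hours,rest_kd_hours stage durations in hours.
#' @export
canonical_protocol <- function(conversion_hours = 504,
                               fibroblast_hours = 72, rest_kd_hours = 72) {
  grn_protocol(data.frame(
    name = c("fibroblast", "rest_kd", "conversion"),
    duration = c(fibroblast_hours, rest_kd_hours, conversion_hours),
    inputs = I(list(character(), "RESTi", c("RESTi", "vAscl1"))),
    stringsAsFactors = FALSE))
}

#' Default initial-state policy for the three protocol stages
#'
#' The fibroblast and REST-knockdown stages start at the measured baseline
#' (relative concentration 1 for PTB, nPTB, miRs and RESTc; 0 for
#' endogenous Ascl1, which is below detection in fibroblasts).  The
#' conversion stage starts from the observed day-3 post-knockdown medians
#' when a dataset is supplied (`conversion = "observed"`), otherwise it
#' carries over the final REST-knockdown state (`"carry"`).  Any entry may
#' instead be an explicit named state vector.
#'
#' @param nodes node names.
#' @param conversion `"observed"`, `"carry"` or a named numeric state.
#' @return a named list of per-stage policies.
#' @export
initial_policy <- function(nodes = GRN_NODES, conversion = "observed") {
  baseline <- setNames(rep(1, length(nodes)), nodes)
  if ("Ascl1" %in% nodes) baseline[["Ascl1"]] <- 0
  list(fibroblast = baseline, rest_kd = baseline, conversion = conversion)
}
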
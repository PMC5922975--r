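#' Behavior class table
#'
#' The canonical coding of Hydra behaviors: the none class is 0 and the ten
#' behaviors are coded 1-10 with larger codes corresponding to more
#' prominent behaviors (prominence drives the window-label aggregation rule
#' and all tie-breaks).
#'
#' @return data.frame with columns \code{code}, \code{name},
#'   \code{prominence}.
#' @export
#' @examples
#' behaviorClasses()
behaviorClasses <- function() {
  data.frame(
    code = 0:10,
    name = c("none", "silent", "elongation", "tentacle_sway", "body_sway",
             "bending", "contraction", "somersaulting", "feeding_writhing",
             "feeding_ball", "feeding_mouth"),
    prominence = 0:10,
    stringsAsFactors = FALSE)
}

#' The six basic behaviors used for desk-scale analyses
#' @return integer behavior codes
#' @export
basicBehaviorCodes <- function() {
  cl <- behaviorClasses()
  cl$code[cl$name %in% c("silent", "elongation", "tentacle_sway",
                         "body_sway", "bending", "contraction")]
}

#' @rdname behaviorClasses
#' @param code integer behavior code(s)
#' @export
behaviorName <- function(code) {
  cl <- behaviorClasses()
  cl$name[match(code, cl$code)]
}

#' @rdname behaviorClasses
#' @param name behavior name(s)
#' @export
behaviorCode <- function(name) {
  cl <- behaviorClasses()
  out <- cl$code[match(name, cl$name)]
  if (anyNA(out))
    stop("unknown behavior name: ", paste(name[is.na(out)], collapse = ", "))
  out
}

prominenceOf <- function(code) {
  cl <- behaviorClasses()
  cl$prominence[match(code, cl$code)]
}
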
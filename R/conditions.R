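#' Experimental conditions
#'
#' The main task is a 2-by-2 design crossing adaptation (No-Adapt vs. Adapt)
#' with response instruction (See: report the percept; Believe: report the
#' best guess about the true stimulus, discounting any known distortion).
#' A control experiment replaces the Believe conditions with explicit
#' response-bias instructions (Bias).
#'
#' @format `main_conditions()` returns the four main condition labels in
#'   canonical order; `all_conditions()` additionally includes the two
#'   control-experiment labels.
#' @return Character vector of condition labels.
#' @export
main_conditions <- function() {
  c("NoAdaptSee", "NoAdaptBelieve", "AdaptSee", "AdaptBelieve")
}

#' @rdname main_conditions
#' @export
all_conditions <- function() {
  c(main_conditions(), "NoAdaptBias", "AdaptBias")
}

#' Is a condition an Adapt condition?
#'
#' @param condition character vector of condition labels.
#' @return Logical vector, `TRUE` where the adaptor was shown.
#' @export
is_adapt_condition <- function(condition) {
  startsWith(as.character(condition), "Adapt")
}

# Internal: validate a vector of condition labels.
check_conditions <- function(condition) {
  bad <- !(condition %in% all_conditions())
  if (any(bad)) {
    stop("unknown condition label(s) at row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "),
         ": ", paste(unique(condition[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
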
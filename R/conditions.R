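#' Experimental conditions
#'
#' The paradigm crosses attention type (endogenous: the agent deliberately
#' looks for something; exogenous: the agent's attention is captured) with
#' agent (self vs other), plus a nonsocial control in which the agent is
#' replaced by an object. Five condition labels exist; the four social
#' labels factor into attention x agent.
#'
#' @format Character vector of the five condition labels.
#' @export
CONDITIONS <- c("endo_self", "exo_self", "endo_other", "exo_other", "nonsocial")

#' @rdname CONDITIONS
#' @export
SOCIAL_CONDITIONS <- CONDITIONS[1:4]

#' Factor structure of the condition labels
#'
#' Map condition labels to their attention type (`"endo"`/`"exo"`), agent
#' (`"self"`/`"other"`) or social status. The nonsocial control maps to `NA`
#' for attention and agent.
#'
#' @param condition character vector of condition labels.
#' @return character (or logical, for `is_social`) vector of the same length.
#' @export
condition_attention <- function(condition) {
  out <- rep(NA_character_, length(condition))
  out[condition %in% c("endo_self", "endo_other")] <- "endo"
  out[condition %in% c("exo_self", "exo_other")] <- "exo"
  out
}

#' @rdname condition_attention
#' @export
condition_agent <- function(condition) {
  out <- rep(NA_character_, length(condition))
  out[condition %in% c("endo_self", "exo_self")] <- "self"
  out[condition %in% c("endo_other", "exo_other")] <- "other"
  out
}

#' @rdname condition_attention
#' @export
is_social <- function(condition) condition %in% SOCIAL_CONDITIONS

#' Binary class labels for a named contrast
#'
#' Translates trial condition labels into the two-class labels of a decoding
#' contrast. Trials that do not belong to the contrast get `NA`. Supported
#' contrasts:
#' * `"endo_vs_exo"` — attention type, over the four social conditions;
#' * `"self_vs_other"` — agent, over the four social conditions;
#' * `"<condA>_vs_<condB>"` for any two condition labels, e.g.
#'   `"endo_self_vs_nonsocial"` (the social-vs-nonsocial decodings);
#' * a length-2 character vector of condition labels.
#'
#' @param condition character vector of condition labels.
#' @param contrast contrast name or a length-2 vector of condition labels.
#' @return factor with two levels (first level = class A of the contrast),
#'   `NA` for out-of-contrast trials.
#' @export
contrast_labels <- function(condition, contrast) {
  if (length(contrast) == 2) {
    lev <- contrast
    lab <- ifelse(condition %in% lev, condition, NA_character_)
    return(factor(lab, levels = lev))
  }
  stopifnot(is.character(contrast), length(contrast) == 1)
  if (contrast == "endo_vs_exo") {
    return(factor(condition_attention(condition), levels = c("endo", "exo")))
  }
  if (contrast == "self_vs_other") {
    return(factor(condition_agent(condition), levels = c("self", "other")))
  }
  for (a in CONDITIONS) {
    pre <- paste0(a, "_vs_")
    if (startsWith(contrast, pre)) {
      b <- substring(contrast, nchar(pre) + 1)
      if (b %in% CONDITIONS) return(contrast_labels(condition, c(a, b)))
    }
  }
  stop("unknown contrast: ", contrast)
}
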
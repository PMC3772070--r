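#' Construct a smoking-mention rule set
#'
#' A rule set bundles the lexicons and scope parameters driving mention
#' detection and classification. All lexicon entries are regular expressions
#' matched case-insensitively at word boundaries within a single sentence.
#' The defaults are a reconstruction of a precision-first clinical smoking
#' annotator: the architecture (keyword presence/absence, sentence-bounded
#' negation and temporality scope, non-tobacco exclusion, abstention on
#' conflict) is fixed; the word lists are configurable because no canonical
#' inventory exists.
#'
#' `tobacco_terms` is split conceptually into smoking *verbs*
#' (smoke/smokes/smoked/smoking), which take an object, and explicit tobacco
#' *products* (cigarette, tobacco, nicotine, ...). A verb mention whose
#' nearest object within `max_tokens` is a `non_tobacco_terms` match
#' (cannabis, cocaine, ...) is suppressed; when the object is a tobacco
#' product, the product anchors the mention and the verb is dropped to avoid
#' double counting.
#'
#' @param tobacco_terms,non_tobacco_terms,negation_cues,past_cues,current_cues
#'   character vectors of regular expressions (see Details for defaults).
#' @param third_party_terms cues indicating the mention concerns someone other
#'   than the patient (mother, family, ...); such mentions are abstained from.
#' @param uncertainty_cues cues indicating unresolved status (unclear,
#'   unknown); abstained from.
#' @param max_tokens maximum number of word tokens between a cue and the
#'   tobacco term for the cue to scope it (same sentence only). Must be >= 1.
#' @param abstain logical; when `TRUE` (default) mentions with conflicting or
#'   absent cues produce no annotation. When `FALSE` every surviving candidate
#'   is annotated, defaulting unresolved mentions to `"current"` — this trades
#'   precision for recall and exists for evaluation experiments.
#' @return an object of class `smoking_ruleset`.
#' @examples
#' rs <- smoking_ruleset()
#' annotate_document(clinical_document("d1", "p1", "2010-01-01",
#'   "assessment", "She has never smoked."), rs)
#' @export
smoking_ruleset <- function(tobacco_terms = NULL,
                            non_tobacco_terms = NULL,
                            negation_cues = NULL,
                            past_cues = NULL,
                            current_cues = NULL,
                            third_party_terms = NULL,
                            uncertainty_cues = NULL,
                            max_tokens = 5L,
                            abstain = TRUE) {
  rs <- list(
    tobacco_terms = tobacco_terms %||% c(
      "smokes", "smoked", "smoking", "smoke",
      "smoker", "smokers",
      "cigarette", "cigarettes", "cigs?", "tobacco", "nicotine",
      "roll-ups?", "rollups?"
    ),
    non_tobacco_terms = non_tobacco_terms %||% c(
      "cannabis", "marijuana", "weed", "skunk", "cocaine", "crack",
      "joints?", "spliffs?", "heroin"
    ),
    negation_cues = negation_cues %||% c(
      "never", "denies", "denied", "no history of", "no hx of",
      "does not", "doesn't", "not a", "non", "no"
    ),
    past_cues = past_cues %||% c(
      "ex", "former", "quit", "stopped", "used to", "gave up",
      "previously", "in the past"
    ),
    current_cues = current_cues %||% c(
      "currently", "current", "per day", "a day", "heavy", "heavily",
      "daily", "continues to", "smokes"
    ),
    third_party_terms = third_party_terms %||% c(
      "mother", "father", "mum", "dad", "wife", "husband", "partner",
      "family", "sister", "brother", "friend", "flatmate", "parents"
    ),
    uncertainty_cues = uncertainty_cues %||% c(
      "unclear", "unknown", "uncertain", "not documented", "\\?"
    ),
    max_tokens = as.integer(max_tokens),
    abstain = isTRUE(abstain)
  )
  class(rs) <- "smoking_ruleset"
  validate_ruleset(rs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_ruleset <- function(rs) {
  stopifnot(inherits(rs, "smoking_ruleset"))
  for (f in c("tobacco_terms", "negation_cues", "past_cues", "current_cues")) {
    if (length(rs[[f]]) == 0L) {
      stop("ruleset field '", f, "' must be non-empty", call. = FALSE)
    }
  }
  if (length(intersect(tolower(rs$tobacco_terms),
                       tolower(rs$non_tobacco_terms))) > 0L) {
    stop("tobacco_terms and non_tobacco_terms must be disjoint", call. = FALSE)
  }
  if (is.na(rs$max_tokens) || rs$max_tokens < 1L) {
    stop("max_tokens must be >= 1", call. = FALSE)
  }
  rs
}

#' @export
print.smoking_ruleset <- function(x, ...) {
  cat("<smoking_ruleset>\n")
  cat("  tobacco terms:    ", length(x$tobacco_terms), "patterns\n")
  cat("  non-tobacco terms:", length(x$non_tobacco_terms), "patterns\n")
  cat("  cues: ", length(x$negation_cues), "negation,",
      length(x$past_cues), "past,",
      length(x$current_cues), "current\n")
  cat("  scope: same sentence, <=", x$max_tokens, "tokens\n")
  cat("  abstention:", if (x$abstain) "enabled" else "disabled", "\n")
  invisible(x)
}

#' Read or write a rule set as JSON
#'
#' Rule sets round-trip losslessly through a JSON document of named lists,
#' so that lexicons can be versioned and overridden from the command line.
#'
#' @param path file path.
#' @param ruleset a `smoking_ruleset`.
#' @return `read_ruleset` returns a validated `smoking_ruleset`;
#'   `write_ruleset` returns `path` invisibly.
#' @export
read_ruleset <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  smoking_ruleset(
    tobacco_terms = raw$tobacco_terms,
    non_tobacco_terms = raw$non_tobacco_terms,
    negation_cues = raw$negation_cues,
    past_cues = raw$past_cues,
    current_cues = raw$current_cues,
    third_party_terms = raw$third_party_terms,
    uncertainty_cues = raw$uncertainty_cues,
    max_tokens = raw$max_tokens %||% 5L,
    abstain = raw$abstain %||% TRUE
  )
}

#' @rdname read_ruleset
#' @export
write_ruleset <- function(ruleset, path) {
  validate_ruleset(ruleset)
  jsonlite::write_json(unclass(ruleset), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
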
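#' A single clinical free-text document
#'
#' Lightweight constructor for a one-row corpus data frame. A corpus is any
#' data frame with columns `doc_id`, `patient_id`, `date`, `doc_type`, `text`;
#' `doc_id` must be unique within a corpus.
#'
#' @param doc_id,patient_id opaque identifiers.
#' @param date document date (`Date` or ISO-8601 string).
#' @param doc_type one of `"assessment"`, `"progress_note"`,
#'   `"correspondence"`.
#' @param text free text; may be empty.
#' @return a one-row data frame usable wherever a corpus is expected.
#' @export
clinical_document <- function(doc_id, patient_id, date, doc_type, text) {
  doc_type <- match.arg(doc_type,
                        c("assessment", "progress_note", "correspondence"))
  data.frame(doc_id = as.character(doc_id),
             patient_id = as.character(patient_id),
             date = as.Date(date),
             doc_type = doc_type,
             text = as.character(text),
             stringsAsFactors = FALSE)
}

# Abbreviations that must not terminate a sentence.
.ABBREV <- c("e.g.", "i.e.", "etc.", "dr.", "mr.", "mrs.", "ms.", "prof.",
             "vs.", "cf.", "approx.", "hx.", "pt.")

#' Split text into sentence spans
#'
#' Sentences are bounded by `.`, `!` or `?` followed by whitespace or end of
#' text, and by newlines (clinical notes are line-structured). Common
#' abbreviations (`e.g.`, `Dr.`, single initials) do not split. Offsets are
#' 0-based, half-open, into the original text; spans are trimmed of
#' surrounding whitespace, non-overlapping, ordered, and jointly cover all
#' non-whitespace characters.
#'
#' @param text a character scalar (possibly empty).
#' @return a data frame with columns `start`, `end` (0-based half-open) and
#'   `sentence`; zero rows for empty or all-whitespace input.
#' @examples
#' segment_sentences("He smokes. She does not.")
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(0), end = integer(0),
                      sentence = character(0), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)

  n <- nchar(text)
  cuts <- integer(0)  # 1-based index of last char of each sentence chunk

  m <- gregexpr("[.!?]+(?=[[:space:]]|$)", text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      s <- as.integer(m)[ends == e][1]
      # word immediately preceding the punctuation, dots included
      pre <- sub(".*[[:space:]]", "", substr(text, 1L, s - 1L))
      word <- tolower(paste0(pre, substr(text, s, e)))
      if (word %in% .ABBREV) next
      if (grepl("^[a-z]\\.$", word)) next  # single initial
      cuts <- c(cuts, e)
    }
  }
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  if (nl[1] != -1L) cuts <- c(cuts, as.integer(nl))
  cuts <- sort(unique(c(cuts, n)))

  out <- empty
  prev <- 0L
  for (cut in cuts) {
    chunk <- substr(text, prev + 1L, cut)
    first_nw <- regexpr("[^[:space:]]", chunk)
    if (first_nw != -1L) {
      last_nw <- regexpr("[^[:space:]][[:space:]]*$", chunk)
      s1 <- prev + as.integer(first_nw)          # 1-based inclusive
      e1 <- prev + as.integer(last_nw)           # 1-based inclusive
      out <- rbind(out, data.frame(start = s1 - 1L, end = e1,
                                   sentence = substr(text, s1, e1),
                                   stringsAsFactors = FALSE))
    }
    prev <- cut
  }
  out
}

# 1-based inclusive spans of word tokens in a string.
token_spans <- function(text) {
  m <- gregexpr("[A-Za-z0-9']+", text)[[1]]
  if (m[1] == -1L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Number of word tokens strictly between two 1-based inclusive spans.
token_distance <- function(tok, a_start, a_end, b_start, b_end) {
  if (a_start > b_start) {
    tmp <- c(a_start, a_end); a_start <- b_start; a_end <- b_end
    b_start <- tmp[1]; b_end <- tmp[2]
  }
  as.integer(sum(tok[, "start"] > a_end & tok[, "end"] < b_start))
}

# Wrap a lexicon pattern with word boundaries where they make sense.
cue_regex <- function(pat) {
  pre <- if (grepl("^[A-Za-z0-9]", pat)) "\\b" else ""
  post <- if (grepl("[A-Za-z0-9?]$", pat) && !grepl("\\\\\\?$", pat)) "\\b" else ""
  paste0(pre, pat, post)
}

.LEXICON_FIELDS <- c("tobacco_terms", "non_tobacco_terms", "negation_cues",
                     "past_cues", "current_cues", "third_party_terms",
                     "uncertainty_cues")

compile_lexicon <- function(patterns) {
  regex <- vapply(patterns, cue_regex, character(1), USE.NAMES = FALSE)
  list(patterns = patterns, regex = regex,
       combined = paste0("(?:", paste(regex, collapse = "|"), ")"))
}

# Precompile per-lexicon regexes once per ruleset; hot loops reuse them.
ensure_compiled <- function(rs) {
  if (is.null(rs$compiled)) {
    rs$compiled <- lapply(rs[.LEXICON_FIELDS], compile_lexicon)
  }
  rs
}

.EMPTY_HITS <- data.frame(start = integer(0), end = integer(0),
                          pattern = character(0), stringsAsFactors = FALSE)

# All case-insensitive matches of a compiled lexicon within a string,
# deduplicated so overlapping matches keep the leftmost-longest. 1-based
# inclusive offsets.
match_lexicon <- function(text, lex) {
  if (is.character(lex)) lex <- compile_lexicon(lex)
  if (length(lex$patterns) == 0L ||
      !grepl(lex$combined, text, ignore.case = TRUE, perl = TRUE)) {
    return(.EMPTY_HITS)
  }
  starts <- integer(0); ends <- integer(0); pats <- character(0)
  for (i in seq_along(lex$patterns)) {
    m <- gregexpr(lex$regex[i], text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- c(starts, as.integer(m))
    ends <- c(ends, as.integer(m) + attr(m, "match.length") - 1L)
    pats <- c(pats, rep(lex$patterns[i], length(m)))
  }
  if (length(starts) == 0L) return(.EMPTY_HITS)
  o <- order(starts, -ends)
  starts <- starts[o]; ends <- ends[o]; pats <- pats[o]
  keep <- rep(TRUE, length(starts))
  last_end <- 0L
  for (i in seq_along(starts)) {
    if (starts[i] <= last_end) keep[i] <- FALSE
    else last_end <- ends[i]
  }
  data.frame(start = starts[keep], end = ends[keep], pattern = pats[keep],
             stringsAsFactors = FALSE)
}

.VERB_FORMS <- c("smoke", "smokes", "smoked", "smoking")

#' Find candidate tobacco mentions in one sentence
#'
#' Matches `tobacco_terms` case-insensitively and applies the non-tobacco
#' exclusion: a smoking *verb* (smoke/smokes/smoked/smoking) whose nearest
#' object within `max_tokens` is a non-tobacco substance (cannabis, cocaine,
#' ...) is suppressed; when the nearest object is an explicit tobacco product
#' the product anchors the mention and the verb is dropped. A product term
#' immediately preceded by a non-tobacco modifier ("cannabis joints") is also
#' suppressed.
#'
#' @param sentence sentence text (as returned by [segment_sentences()]).
#' @param rules a [smoking_ruleset()].
#' @return data frame with 1-based inclusive columns `start`, `end` plus
#'   `matched_text` and `is_verb`, offsets relative to `sentence`.
#' @export
find_candidate_mentions <- function(sentence, rules) {
  validate_ruleset(rules)
  rules <- ensure_compiled(rules)
  tob <- match_lexicon(sentence, rules$compiled$tobacco_terms)
  if (nrow(tob) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      matched_text = character(0), is_verb = logical(0),
                      stringsAsFactors = FALSE))
  }
  tob$matched_text <- substring(sentence, tob$start, tob$end)
  tob$is_verb <- tolower(tob$matched_text) %in% .VERB_FORMS
  non <- match_lexicon(sentence, rules$compiled$non_tobacco_terms)
  tok <- token_spans(sentence)
  keep <- rep(TRUE, nrow(tob))

  for (i in seq_len(nrow(tob))) {
    if (tob$is_verb[i]) {
      # nearest following object: product term or non-tobacco substance
      objs <- rbind(
        if (nrow(tob) > 1L)
          data.frame(start = tob$start[-i], end = tob$end[-i],
                     tobacco = !tob$is_verb[-i])[!tob$is_verb[-i], , drop = FALSE]
        else NULL,
        if (nrow(non) > 0L)
          data.frame(start = non$start, end = non$end, tobacco = FALSE)
        else NULL)
      if (!is.null(objs) && nrow(objs) > 0L) {
        objs <- objs[objs$start > tob$end[i], , drop = FALSE]
        if (nrow(objs) > 0L) {
          objs <- objs[order(objs$start), , drop = FALSE]
          d <- token_distance(tok, tob$start[i], tob$end[i],
                              objs$start[1], objs$end[1])
          if (d <= rules$max_tokens) keep[i] <- FALSE
        }
      }
    } else if (nrow(non) > 0L) {
      # product directly modified by a non-tobacco term ("cannabis cigarettes")
      adj <- any(non$end < tob$start[i] &
                   vapply(seq_len(nrow(non)), function(j) {
                     non$end[j] < tob$start[i] &&
                       token_distance(tok, non$start[j], non$end[j],
                                      tob$start[i], tob$end[i]) == 0L
                   }, logical(1)))
      if (adj) keep[i] <- FALSE
    }
  }
  tob <- tob[keep, c("start", "end", "matched_text", "is_verb"), drop = FALSE]
  rownames(tob) <- NULL
  tob
}

# Cue hits of one category within scope of a candidate span; excludes hits
# overlapping the candidate itself.
cues_in_scope <- function(sentence, tok, lex, c_start, c_end, max_tokens) {
  hits <- match_lexicon(sentence, lex)
  if (nrow(hits) == 0L) return(hits)
  overlap <- hits$start <= c_end & hits$end >= c_start
  hits <- hits[!overlap, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  d <- vapply(seq_len(nrow(hits)), function(j) {
    token_distance(tok, hits$start[j], hits$end[j], c_start, c_end)
  }, integer(1))
  hits[d <= max_tokens, , drop = FALSE]
}

#' Classify one candidate mention
#'
#' Applies negation, temporality and experiencer cues within the sentence and
#' within `max_tokens` of the candidate. Exactly one cue category present
#' resolves the status (never/past/current); a bare third-person present-tense
#' verb ("smokes") with no explicit cue asserts current smoking. Conflicting
#' cue categories, third-party experiencers ("family smokes"), uncertainty
#' markers, or an unresolved bare mention lead to abstention (`NULL`) when
#' `rules$abstain` is `TRUE`, or to a default `"current"` annotation when
#' abstention is disabled.
#'
#' @param candidate one row of [find_candidate_mentions()] output.
#' @param sentence the sentence text the candidate lies in.
#' @param rules a [smoking_ruleset()].
#' @return a one-row data frame (`status`, `rule_id`, offsets relative to the
#'   sentence) or `NULL` on abstention.
#' @export
classify_mention <- function(candidate, sentence, rules) {
  validate_ruleset(rules)
  rules <- ensure_compiled(rules)
  tok <- token_spans(sentence)
  scope <- function(field) {
    cues_in_scope(sentence, tok, rules$compiled[[field]],
                  candidate$start, candidate$end, rules$max_tokens)
  }
  neg <- scope("negation_cues")
  pas <- scope("past_cues")
  cur <- scope("current_cues")
  oth <- scope("third_party_terms")
  unc <- scope("uncertainty_cues")

  decide <- function(status, rule_id) {
    data.frame(start = candidate$start, end = candidate$end,
               matched_text = candidate$matched_text,
               status = status, rule_id = rule_id,
               stringsAsFactors = FALSE)
  }
  fallback <- if (rules$abstain) NULL else decide("current", "current:default")

  if (nrow(oth) > 0L || nrow(unc) > 0L) return(fallback)
  present <- c(never = nrow(neg) > 0L, past = nrow(pas) > 0L,
               current = nrow(cur) > 0L)
  if (sum(present) > 1L) return(fallback)
  if (present[["never"]]) return(decide("never", paste0("never:", neg$pattern[1])))
  if (present[["past"]]) return(decide("past", paste0("past:", pas$pattern[1])))
  if (present[["current"]]) return(decide("current", paste0("current:", cur$pattern[1])))
  if (tolower(candidate$matched_text) == "smokes") {
    return(decide("current", "current:present_tense"))
  }
  fallback
}

empty_annotations <- function() {
  data.frame(doc_id = character(0), start = integer(0), end = integer(0),
             matched_text = character(0), status = character(0),
             rule_id = character(0), stringsAsFactors = FALSE)
}

#' Annotate a document with smoking-status mentions
#'
#' Runs sentence segmentation, candidate detection and classification over a
#' document and returns mention-level annotations ordered by start offset.
#' Offsets are 0-based half-open into the original document text, so
#' `substr(text, start + 1, end)` recovers `matched_text`. Deterministic for
#' fixed inputs.
#'
#' @param doc a one-row corpus data frame (see [clinical_document()]).
#' @param rules a [smoking_ruleset()].
#' @return data frame with columns `doc_id`, `start`, `end`, `matched_text`,
#'   `status`, `rule_id`.
#' @export
annotate_document <- function(doc, rules = smoking_ruleset()) {
  stopifnot(is.data.frame(doc), nrow(doc) == 1L,
            all(c("doc_id", "text") %in% names(doc)))
  validate_ruleset(rules)
  rules <- ensure_compiled(rules)
  rows <- list()
  sents <- segment_sentences(doc$text)
  for (i in seq_len(nrow(sents))) {
    sent <- sents$sentence[i]
    cands <- find_candidate_mentions(sent, rules)
    for (j in seq_len(nrow(cands))) {
      ann <- classify_mention(cands[j, , drop = FALSE], sent, rules)
      if (is.null(ann)) next
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = doc$doc_id,
        start = sents$start[i] + ann$start - 1L,   # to 0-based document offset
        end = sents$start[i] + ann$end,            # half-open
        matched_text = ann$matched_text,
        status = ann$status, rule_id = ann$rule_id,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(list(empty_annotations()), rows))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate every document in a corpus
#'
#' @param corpus data frame with columns `doc_id`, `patient_id`, `date`,
#'   `doc_type`, `text`; `doc_id` must be unique.
#' @param rules a [smoking_ruleset()].
#' @return row-bound [annotate_document()] output for all documents.
#' @export
annotate_corpus <- function(corpus, rules = smoking_ruleset()) {
  stopifnot(is.data.frame(corpus),
            all(c("doc_id", "patient_id", "date", "text") %in% names(corpus)))
  if (anyDuplicated(corpus$doc_id)) {
    stop("doc_id must be unique within a corpus", call. = FALSE)
  }
  rules <- ensure_compiled(validate_ruleset(rules))
  res <- lapply(seq_len(nrow(corpus)), function(i) {
    annotate_document(corpus[i, , drop = FALSE], rules)
  })
  out <- do.call(rbind, c(list(empty_annotations()), res))
  rownames(out) <- NULL
  out
}
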
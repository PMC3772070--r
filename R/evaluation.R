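#' Match predicted annotations against gold annotations
#'
#' One-to-one matching per document: a predicted/gold pair matches when the
#' statuses agree and the spans satisfy the matching criterion (`"overlap"`,
#' any shared character, the default; or `"exact"`, identical offsets).
#' Matching is greedy over candidate pairs ordered leftmost-longest with
#' deterministic tie-breaking, so it is invariant to input row order.
#'
#' @param predicted,gold annotation data frames with columns `doc_id`,
#'   `start`, `end`, `status` (0-based half-open offsets). `predicted` may
#'   also carry `rule_id`.
#' @param matching `"overlap"` or `"exact"`.
#' @param doc_ids optional character vector of known document ids; annotations
#'   referencing other documents are an error.
#' @return list with data frames `pairs` (indices into the two inputs),
#'   `fp` (unmatched predicted rows), `fn` (unmatched gold rows).
#' @export
match_annotations <- function(predicted, gold,
                              matching = c("overlap", "exact"),
                              doc_ids = NULL) {
  matching <- match.arg(matching)
  req <- c("doc_id", "start", "end", "status")
  stopifnot(all(req %in% names(predicted)), all(req %in% names(gold)))
  if (!is.null(doc_ids)) {
    unknown <- setdiff(c(predicted$doc_id, gold$doc_id), doc_ids)
    if (length(unknown) > 0L) {
      stop("annotations reference unknown doc_ids: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
  }
  np <- nrow(predicted); ng <- nrow(gold)
  cand <- NULL
  if (np > 0L && ng > 0L) {
    cand <- do.call(rbind, lapply(seq_len(np), function(i) {
      ok <- gold$doc_id == predicted$doc_id[i] &
        gold$status == predicted$status[i] &
        (if (matching == "exact")
           gold$start == predicted$start[i] & gold$end == predicted$end[i]
         else
           gold$start < predicted$end[i] & gold$end > predicted$start[i])
      if (!any(ok)) return(NULL)
      data.frame(p = i, g = which(ok))
    }))
  }
  pairs <- data.frame(p = integer(0), g = integer(0))
  if (!is.null(cand) && nrow(cand) > 0L) {
    # leftmost-longest, symmetric in the two sets up to a final deterministic
    # tie-break
    lo <- pmin(predicted$start[cand$p], gold$start[cand$g])
    hi <- pmax(predicted$end[cand$p], gold$end[cand$g])
    ov <- pmin(predicted$end[cand$p], gold$end[cand$g]) -
      pmax(predicted$start[cand$p], gold$start[cand$g])
    o <- order(predicted$doc_id[cand$p], lo, -ov, hi,
               predicted$start[cand$p], gold$start[cand$g])
    cand <- cand[o, , drop = FALSE]
    used_p <- logical(np); used_g <- logical(ng)
    for (r in seq_len(nrow(cand))) {
      i <- cand$p[r]; j <- cand$g[r]
      if (!used_p[i] && !used_g[j]) {
        used_p[i] <- TRUE; used_g[j] <- TRUE
        pairs <- rbind(pairs, data.frame(p = i, g = j))
      }
    }
  }
  fp_idx <- setdiff(seq_len(np), pairs$p)
  fn_idx <- setdiff(seq_len(ng), pairs$g)
  list(pairs = pairs,
       fp = predicted[fp_idx, , drop = FALSE],
       fn = gold[fn_idx, , drop = FALSE])
}

#' Annotation-level precision and recall
#'
#' Scores predicted annotations against gold at the annotation (mention)
#' level: precision = tp / (tp + fp) (positive predictive value), recall =
#' tp / (tp + fn) (sensitivity). A predicted/gold pair with overlapping spans
#' but disagreeing status is unmatched on both sides, i.e. counted as one
#' false positive *and* one false negative. Undefined metrics (zero
#' denominator) are `NA` with `undefined` flags.
#'
#' @inheritParams match_annotations
#' @return object of class `eval_result`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `by_class` (per-status counts), `fp_by_rule` (false-positive
#'   counts per firing rule, when `predicted` has `rule_id`), plus the
#'   unmatched row sets `fp_rows`, `fn_rows`.
#' @export
score_annotations <- function(predicted, gold,
                              matching = c("overlap", "exact"),
                              doc_ids = NULL) {
  m <- match_annotations(predicted, gold, matching, doc_ids)
  tp <- nrow(m$pairs); fp <- nrow(m$fp); fn <- nrow(m$fn)
  by_class <- lapply(.STATUS_LEVELS, function(s) {
    tps <- if (tp > 0L) sum(gold$status[m$pairs$g] == s) else 0L
    c(tp = tps,
      fp = sum(m$fp$status == s),
      fn = sum(m$fn$status == s))
  })
  names(by_class) <- .STATUS_LEVELS
  fp_by_rule <- if ("rule_id" %in% names(m$fp) && nrow(m$fp) > 0L) {
    sort(table(m$fp$rule_id), decreasing = TRUE)
  } else NULL
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    undefined = c(precision = tp + fp == 0L, recall = tp + fn == 0L),
    by_class = by_class, fp_by_rule = fp_by_rule,
    fp_rows = m$fp, fn_rows = m$fn),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> tp:", x$tp, " fp:", x$fp, " fn:", x$fn, "\n")
  cat("  precision:",
      if (x$undefined["precision"]) "undefined" else sprintf("%.3f", x$precision),
      " recall:",
      if (x$undefined["recall"]) "undefined" else sprintf("%.3f", x$recall),
      "\n")
  invisible(x)
}

#' Human-readable error listing for rule development
#'
#' Lists every false positive and false negative once, with its document id,
#' span, status, the matched/expected text snippet with sentence context,
#' and (for false positives) the rule that fired.
#'
#' @param result an [score_annotations()] result.
#' @param corpus the corpus the annotations refer to (for context snippets).
#' @param context_chars characters of context either side of the span.
#' @return data frame `kind` (fp/fn), `doc_id`, `start`, `end`, `status`,
#'   `rule_id`, `snippet`; zero rows for a perfect evaluation.
#' @export
error_report <- function(result, corpus, context_chars = 30L) {
  stopifnot(inherits(result, "eval_result"))
  snippet <- function(doc_id, start, end) {
    txt <- corpus$text[match(doc_id, corpus$doc_id)]
    lo <- pmax(0L, start - context_chars)
    hi <- pmin(nchar(txt), end + context_chars)
    substr(txt, lo + 1L, hi)
  }
  mk <- function(rows, kind) {
    if (nrow(rows) == 0L) return(NULL)
    data.frame(kind = kind, doc_id = rows$doc_id,
               start = rows$start, end = rows$end, status = rows$status,
               rule_id = if ("rule_id" %in% names(rows)) rows$rule_id
                         else NA_character_,
               snippet = snippet(rows$doc_id, rows$start, rows$end),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(result$fp_rows, "fp"), mk(result$fn_rows, "fn"))
  if (is.null(out)) {
    out <- data.frame(kind = character(0), doc_id = character(0),
                      start = integer(0), end = integer(0),
                      status = character(0), rule_id = character(0),
                      snippet = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
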
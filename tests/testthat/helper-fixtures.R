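# Shared fixture builders. Everything is generated in code; no data files.

doc1 <- function(text, doc_id = "d1", patient_id = "p1",
                 date = "2009-06-01", doc_type = "assessment") {
  clinical_document(doc_id, patient_id, date, doc_type, text)
}

# Small corpus: one document per text, distinct ids/patients.
mini_corpus <- function(texts, dates = "2009-06-01") {
  dates <- rep(as.Date(dates), length.out = length(texts))
  do.call(rbind, lapply(seq_along(texts), function(i) {
    clinical_document(sprintf("d%02d", i), sprintf("p%02d", i),
                      dates[i], "progress_note", texts[i])
  }))
}

# One annotation row in the package schema (0-based half-open offsets).
ann_row <- function(doc_id, start, end, status, rule_id = "r") {
  data.frame(doc_id = doc_id, start = as.integer(start),
             end = as.integer(end),
             matched_text = "x", status = status, rule_id = rule_id,
             stringsAsFactors = FALSE)
}

empty_ann <- function() {
  data.frame(doc_id = character(0), start = integer(0), end = integer(0),
             status = character(0), stringsAsFactors = FALSE)
}

gold_row <- function(doc_id, start, end, status) {
  data.frame(doc_id = doc_id, start = as.integer(start),
             end = as.integer(end), status = status,
             stringsAsFactors = FALSE)
}

# Random small 2 x k count table with all margins positive.
random_2xk <- function(k = 3, max_n = 40) {
  n <- sample(5:max_n, k, replace = TRUE)
  p <- stats::runif(1, 0.15, 0.85)
  r <- stats::rbinom(k, n, p)
  r <- pmin(pmax(r, 1L), n - 1L)  # keep both outcome margins positive
  rbind(success = r, failure = n - r)
}

# A generated register shared across test files (computed once per session).
default_register <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_register(simulation_config(n_patients = 250,
                                                    seed = 20080101))
    }
    cache
  }
})

default_annotations <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- annotate_corpus(default_register()$corpus)
    cache
  }
})
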
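# Synthetic case-register generator: a stated world with demographically
# patterned smoking, documentation and missingness, so the whole pipeline is
# testable without patient data.

.AGE_BANDS <- c("15-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75+")
.AGE_RANGE <- list(c(16, 24), c(25, 34), c(35, 44), c(45, 54), c(55, 64),
                   c(65, 74), c(75, 90))

#' Configuration for the synthetic case-register generator
#'
#' Defaults describe a secondary mental-healthcare referral cohort:
#' demographic marginals of a 1,555-patient severe-mental-illness cohort
#' (seven age bands, slight male excess, mostly single, tertile-split area
#' deprivation, schizophrenia/schizoaffective/bipolar/other diagnoses);
#' current smoking generated from a logistic model in the same covariates
#' (odds ratios around 0.2 for age 65+, 0.6 for female, 1.26 per deprivation
#' tertile); missingness of any smoking record patterned on sex, mid-life
#' age, affluence and bipolar diagnosis; sparse structured-field completion
#' (11.6%) supplemented by free-text mentions.
#'
#' @param n_patients number of patients.
#' @param referral_window length-2 date vector for referral dates.
#' @param age_probs,sex_probs,marital_probs,deprivation_probs,diagnosis_probs
#'   named category probabilities (must sum to 1).
#' @param smoking_coefs named log-odds coefficients of the current-smoking
#'   model: `intercept`, `age65`, `female`, `cohabiting`,
#'   `separated_widowed`, `dep` (per tertile 0/1/2), `schizoaffective`,
#'   `bipolar`, `other`.
#' @param past_given_not_current probability a non-current smoker is a past
#'   (vs never) smoker.
#' @param missing_coefs named log-odds coefficients of the probability that a
#'   patient has *no* smoking record anywhere: `intercept`, `female`,
#'   `age_35_64`, `age_65plus`, `dep_least`, `dep_middle`, `bipolar`.
#' @param docs_lambda documents per patient are `1 + Poisson(docs_lambda)`.
#' @param mention_prob per-document probability that (an ascertainable)
#'   patient's smoking is mentioned.
#' @param out_of_lexicon_prob fraction of smoking mentions phrased outside
#'   the default lexicons (creates honest recall < 1).
#' @param bare_mention_prob fraction of in-lexicon *current* mentions phrased
#'   without any resolving cue (the abstention-recall trade-off).
#' @param distractor_prob per-document probability of a non-tobacco /
#'   third-party / uncertain distractor sentence (never gold-annotated).
#' @param structured_prob probability an ascertainable patient has a
#'   structured smoking-status entry (dated referral + 0-30 days).
#' @param seed integer RNG seed; the same config is byte-identical across
#'   runs.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 1555,
    referral_window = c("2008-01-01", "2011-12-31"),
    age_probs = c("15-24" = 364, "25-34" = 429, "35-44" = 317,
                  "45-54" = 179, "55-64" = 92, "65-74" = 85, "75+" = 89) / 1555,
    sex_probs = c(male = 802, female = 753) / 1555,
    marital_probs = c(single = 1019, cohabiting = 270,
                      separated_widowed = 214, unknown = 52) / 1555,
    deprivation_probs = c(least = 473, middle = 502, most = 465,
                          unknown = 115) / 1555,
    diagnosis_probs = c(schizophrenia = 669, schizoaffective = 62,
                        bipolar = 384, other = 440) / 1555,
    smoking_coefs = c(intercept = 0.85, age65 = log(0.23),
                      female = log(0.62), cohabiting = log(0.53),
                      separated_widowed = 0, dep = log(1.26),
                      schizoaffective = log(1.66), bipolar = log(0.77),
                      other = log(0.58)),
    past_given_not_current = 0.35,
    missing_coefs = c(intercept = -0.85, female = 0.47, age_35_64 = 0.45,
                      age_65plus = -0.75, dep_least = 0.35,
                      dep_middle = 0.10, bipolar = 0.75),
    docs_lambda = 3,
    mention_prob = 0.5,
    out_of_lexicon_prob = 0.25,
    bare_mention_prob = 0.15,
    distractor_prob = 0.30,
    structured_prob = 0.116,
    seed = 42L) {
  cfg <- as.list(environment())
  cfg$referral_window <- as.Date(referral_window)
  for (f in c("age_probs", "sex_probs", "marital_probs",
              "deprivation_probs", "diagnosis_probs")) {
    p <- cfg[[f]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(f, " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  for (f in c("past_given_not_current", "mention_prob",
              "out_of_lexicon_prob", "bare_mention_prob", "distractor_prob",
              "structured_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(f, " must lie in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(cfg$n_patients >= 0, cfg$docs_lambda >= 0)
  class(cfg) <- "simulation_config"
  cfg
}

# Note templates. {{...}} marks the gold-annotated span; `kind` controls the
# phrasing mix: "in" = default-lexicon with resolving cue, "bare" =
# in-lexicon but cueless (engine abstains), "out" = out-of-lexicon (engine
# blind). Distractors and fillers carry no gold annotation.
note_templates <- function() {
  list(
    current_in = c(
      "He is a heavy {{smoker}}.",
      "Currently {{smokes 20 cigarettes}} per day.",
      "She {{smokes}} roughly ten a day.",
      "Current {{smoker}}.",
      "Still smoking {{tobacco}} daily."),
    current_bare = c(
      "{{Smoker}}.",
      "{{Tobacco}} user.",
      "Known to smoke {{cigarettes}} at times."),
    current_out = c(
      "Goes through a pack of {{Marlboro reds}} most days.",
      "Heavy use of {{rollies}} every evening.",
      "Twenty-a-day {{habit}} as per GP letter."),
    past_in = c(
      "{{Ex-smoker}}, quit two years ago.",
      "{{Quit smoking}} in 2009.",
      "Gave up {{cigarettes}} last spring.",
      "Used to {{smoke}} in his twenties."),
    past_out = c(
      "Packed in the {{fags}} years back.",
      "History of {{tobacco use}}, none since 2010."),
    never_in = c(
      "She has {{never smoked}}.",
      "{{Non-smoker}}.",
      "Denies {{smoking}}.",
      "No history of {{tobacco}} use."),
    never_out = c(
      "Has never touched {{a fag}} in her life.",
      "Has always stayed away from {{cigs and the like}}."),
    distractor = c(
      "Smokes cannabis most evenings.",
      "His mother smokes heavily.",
      "Enjoys smoked salmon from the market.",
      "Smoking status unclear.",
      "Uses cannabis joints daily."),
    filler = c(
      "Seen at home today; mood stable.",
      "Attended outpatient clinic as planned.",
      "Medication reviewed with good adherence.",
      "Sleep remains poor but appetite good.",
      "Risk assessment unchanged since last review."))
}

# Strip {{ }} markers; return text plus 0-based half-open gold span (or NULL).
realise_template <- function(tpl) {
  open <- regexpr("{{", tpl, fixed = TRUE)
  if (open == -1L) return(list(text = tpl, span = NULL))
  close <- regexpr("}}", tpl, fixed = TRUE)
  inner <- substr(tpl, open + 2L, close - 1L)
  text <- paste0(substr(tpl, 1L, open - 1L), inner,
                 substr(tpl, close + 2L, nchar(tpl)))
  list(text = text,
       span = c(start = open - 1L, end = open - 1L + nchar(inner)))
}

plogis_lin <- function(x) 1 / (1 + exp(-x))

# Patient layer only: demographics + true smoking status + missingness flag.
# Used directly by parameter-recovery simulations.
#' @rdname generate_register
#' @export
simulate_patients <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_patients
  draw <- function(probs) {
    if (n == 0L) return(character(0))
    sample(names(probs), n, replace = TRUE, prob = probs)
  }
  band <- draw(config$age_probs)
  idx <- match(band, .AGE_BANDS)
  age <- vapply(idx, function(i) {
    r <- .AGE_RANGE[[i]]; sample(r[1]:r[2], 1L)
  }, numeric(1))
  sex <- draw(config$sex_probs)
  marital <- draw(config$marital_probs)
  dep <- draw(config$deprivation_probs)
  dia <- draw(config$diagnosis_probs)
  w <- config$referral_window
  referral <- w[1] + sample.int(as.integer(w[2] - w[1]) + 1L, n,
                                replace = TRUE) - 1L
  care_days <- round(stats::rexp(n, rate = 1 / 300))
  b <- config$smoking_coefs
  dep_score <- ifelse(dep == "least", 0, ifelse(dep == "middle", 1,
               ifelse(dep == "most", 2, 1)))  # unknown -> middle
  lp <- b["intercept"] + b["age65"] * (age >= 65) +
    b["female"] * (sex == "female") +
    b["cohabiting"] * (marital == "cohabiting") +
    b["separated_widowed"] * (marital == "separated_widowed") +
    b["dep"] * dep_score +
    b["schizoaffective"] * (dia == "schizoaffective") +
    b["bipolar"] * (dia == "bipolar") + b["other"] * (dia == "other")
  current <- stats::runif(n) < plogis_lin(lp)
  status <- ifelse(current, "current",
                   ifelse(stats::runif(n) < config$past_given_not_current,
                          "past", "never"))
  m <- config$missing_coefs
  mlp <- m["intercept"] + m["female"] * (sex == "female") +
    m["age_35_64"] * (age >= 35 & age < 65) +
    m["age_65plus"] * (age >= 65) +
    m["dep_least"] * (dep == "least") + m["dep_middle"] * (dep == "middle") +
    m["bipolar"] * (dia == "bipolar")
  ascertainable <- stats::runif(n) >= plogis_lin(mlp)
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age_at_referral = age, sex = sex, marital = marital,
    deprivation_tertile = dep, diagnosis = dia,
    referral_date = referral,
    care_end_date = referral + care_days,
    age_band = band, dep_score = dep_score,
    true_status = status, ascertainable = ascertainable,
    p_current = plogis_lin(lp),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic case register with gold annotations
#'
#' Draws patients ([simulate_patients()]), then a structured smoking-status
#' table and a free-text document corpus whose smoking phrases are assembled
#' from a template bank covering in-lexicon, cueless and out-of-lexicon
#' phrasings plus non-tobacco / third-party / uncertainty distractors. Every
#' generated smoking phrase carries exactly one gold annotation with exact
#' character offsets; distractors carry none. Patients drawn as
#' non-ascertainable have no structured entry and no smoking mention in any
#' note (the missingness mechanism). Byte-identical output for a fixed
#' config.
#'
#' @param config a [simulation_config()].
#' @return list with data frames `patients` (demographics incl. ground-truth
#'   columns `true_status`, `ascertainable`), `structured`, `corpus`, `gold`
#'   (0-based half-open spans with `status`).
#' @export
generate_register <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pats <- simulate_patients(config)
  n <- nrow(pats)
  tpl <- note_templates()

  structured <- data.frame(patient_id = character(0),
                           date = as.Date(character(0)),
                           status = character(0), stringsAsFactors = FALSE)
  corpus_rows <- list()
  gold_rows <- list()
  doc_counter <- 0L

  for (i in seq_len(n)) {
    if (pats$ascertainable[i] && stats::runif(1) < config$structured_prob) {
      structured <- rbind(structured, data.frame(
        patient_id = pats$patient_id[i],
        date = pats$referral_date[i] + sample(0:30, 1L),
        status = pats$true_status[i], stringsAsFactors = FALSE))
    }
    n_docs <- 1L + stats::rpois(1L, config$docs_lambda)
    span_days <- max(1L, as.integer(pats$care_end_date[i] -
                                      pats$referral_date[i]))
    for (d in seq_len(n_docs)) {
      doc_counter <- doc_counter + 1L
      doc_id <- sprintf("D%06d", doc_counter)
      sents <- sample(tpl$filler, 1L)
      golds <- NULL
      if (pats$ascertainable[i] && stats::runif(1) < config$mention_prob) {
        st <- pats$true_status[i]
        u <- stats::runif(1)
        kind <- if (u < config$out_of_lexicon_prob) "out"
        else if (st == "current" &&
                 u < config$out_of_lexicon_prob + config$bare_mention_prob)
          "bare"
        else "in"
        pool <- tpl[[paste0(st, "_", kind)]]
        if (is.null(pool)) pool <- tpl[[paste0(st, "_in")]]
        r <- realise_template(sample(pool, 1L))
        golds <- list(list(text = r$text, span = r$span, status = st))
        sents <- c(sents, r$text)
      }
      if (stats::runif(1) < config$distractor_prob) {
        sents <- c(sents, sample(tpl$distractor, 1L))
      }
      sents <- c(sents, sample(tpl$filler, 1L))
      text <- paste(sents, collapse = " ")
      # locate the gold sentence's offset within the assembled note
      if (!is.null(golds)) {
        g <- golds[[1]]
        sent_pos <- regexpr(g$text, text, fixed = TRUE)
        gold_rows[[length(gold_rows) + 1L]] <- data.frame(
          doc_id = doc_id,
          start = as.integer(sent_pos) - 1L + g$span[["start"]],
          end = as.integer(sent_pos) - 1L + g$span[["end"]],
          status = g$status, stringsAsFactors = FALSE)
      }
      corpus_rows[[doc_counter]] <- data.frame(
        doc_id = doc_id, patient_id = pats$patient_id[i],
        date = pats$referral_date[i] +
          sample.int(span_days, 1L) - 1L,
        doc_type = sample(c("assessment", "progress_note",
                            "correspondence"), 1L),
        text = text, stringsAsFactors = FALSE)
    }
  }
  corpus <- do.call(rbind, c(corpus_rows, list(
    data.frame(doc_id = character(0), patient_id = character(0),
               date = as.Date(character(0)), doc_type = character(0),
               text = character(0), stringsAsFactors = FALSE))))
  gold <- do.call(rbind, c(gold_rows, list(
    data.frame(doc_id = character(0), start = integer(0), end = integer(0),
               status = character(0), stringsAsFactors = FALSE))))
  rownames(corpus) <- rownames(gold) <- NULL
  list(patients = pats, structured = structured, corpus = corpus,
       gold = gold)
}

#' Small deterministic fixtures for hand-traceable tests
#'
#' Emits the corner-case corpora the rule engine, resolver and evaluation
#' harness are specified against, each with its expected output: a negated
#' mention, a cannabis-only note, a three-mention note (affirmative +
#' negated + cannabis), and a same-date structured/text conflict.
#'
#' @return named list of fixtures; each has the inputs plus an `expected`
#'   element.
#' @export
make_fixture_suite <- function() {
  list(
    negation = list(
      doc = clinical_document("fx-neg", "pt1", "2009-06-01", "assessment",
                              "She has never smoked."),
      expected = list(n_annotations = 1L, status = "never")),
    cannabis_only = list(
      doc = clinical_document("fx-cann", "pt2", "2009-06-01",
                              "progress_note",
                              "Smokes cannabis most evenings. Uses cannabis joints daily."),
      expected = list(n_annotations = 0L)),
    three_mention = list(
      doc = clinical_document(
        "fx-three", "pt3", "2009-06-01", "assessment",
        paste("He is a heavy smoker. Denies smoking cigarettes.",
              "Smokes cannabis at weekends.")),
      expected = list(n_annotations = 2L,
                      statuses = c("current", "never"))),
    same_date_conflict = list(
      patient = data.frame(patient_id = "pt4", age_at_referral = 30,
                           referral_date = as.Date("2009-01-01"),
                           care_end_date = as.Date("2010-06-01"),
                           stringsAsFactors = FALSE),
      structured = data.frame(patient_id = "pt4",
                              date = as.Date("2009-02-01"),
                              status = "past", stringsAsFactors = FALSE),
      text_records = data.frame(patient_id = "pt4",
                                date = as.Date("2009-02-01"),
                                status = "current",
                                stringsAsFactors = FALSE),
      expected = list(status = "past", source = "structured")))
}
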
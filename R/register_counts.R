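#' Published summary counts from a large mental-health case register
#'
#' Cell counts reported by a study of smoking-status ascertainment in a
#' South London secondary mental-healthcare cohort (referrals 2008-2011 with
#' a severe-mental-illness diagnosis): coverage of any smoking information by
#' source and by referral year, per-category missingness in the 12-month-care
#' cohort (n = 1,555), and current-smoking counts among the 995 patients of
#' that cohort with a resolved status. These printed counts are the inputs
#' for reproducing the study's derived statistics (prevalences, trend and
#' heterogeneity tests, odds ratios); individual-level data are not public.
#'
#' @return a list of data frames:
#' \describe{
#'   \item{coverage}{by information source and sample: `n_with_status`,
#'     `n_cohort`.}
#'   \item{by_year}{per referral year: cohort sizes and coverage percentages
#'     under each source regime.}
#'   \item{missingness}{factor, category, `n`, `n_missing` in the 12-month
#'     cohort.}
#'   \item{smoking}{factor, category, `n`, `n_current` among the 995 with
#'     status; ordinal factors carry categories in order.}
#' }
#' @export
register_counts <- function() {
  coverage <- data.frame(
    source = rep(c("structured_only", "structured_plus_text"), 2),
    sample = rep(c("total", "care12m"), each = 2),
    n_with_status = c(547, 2907, 180, 995),
    n_cohort = c(5588, 5588, 1555, 1555),
    stringsAsFactors = FALSE)

  by_year <- data.frame(
    year = c(2008, 2009, 2010),
    n_total = c(1493, 1483, 1396),
    pct_structured_total = c(10.1, 8.7, 9.4),
    pct_combined_total = c(54.9, 51.9, 53.6),
    n_care12m = c(504, 499, 512),
    pct_structured_care12m = c(10.7, 12.2, 11.5),
    pct_combined_care12m = c(64.1, 64.9, 62.9))

  missingness <- data.frame(
    factor = c(rep("age_band", 7), rep("sex", 2), rep("marital", 3),
               rep("deprivation", 3), rep("diagnosis", 4)),
    category = c("15-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75+",
                 "male", "female",
                 "single", "cohabiting", "separated_widowed",
                 "least", "middle", "most",
                 "schizophrenia", "schizoaffective", "bipolar", "other"),
    n = c(364, 429, 317, 179, 92, 85, 89,
          802, 753,
          1019, 270, 214,
          473, 502, 465,
          669, 62, 384, 440),
    n_missing = c(113, 156, 140, 76, 42, 20, 13,
                  247, 313,
                  345, 106, 69,
                  199, 171, 150,
                  213, 20, 189, 138),
    stringsAsFactors = FALSE)

  smoking <- data.frame(
    factor = c(rep("age_band", 7), rep("sex", 2), rep("marital", 3),
               rep("deprivation", 3), rep("diagnosis", 4)),
    category = c("15-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75+",
                 "male", "female",
                 "single", "cohabiting", "separated_widowed",
                 "least", "middle", "most",
                 "schizophrenia", "schizoaffective", "bipolar", "other"),
    n = c(251, 273, 177, 103, 50, 65, 76,
          555, 440,
          674, 164, 145,
          274, 331, 315,
          456, 42, 195, 302),
    n_current = c(172, 170, 109, 69, 33, 18, 22,
                  370, 223,
                  446, 72, 68,
                  147, 194, 204,
                  297, 28, 110, 158),
    stringsAsFactors = FALSE)

  list(coverage = coverage, by_year = by_year, missingness = missingness,
       smoking = smoking)
}

#' Reference-cohort odds ratios and grouped logistic fits from the counts
#'
#' Convenience reconstructions of the derived statistics of the reference
#' cohort from [register_counts()]: the unadjusted 2x2 odds ratios (exposure
#' vs its reference category, current smoking as the event) and the
#' per-tertile deprivation odds ratio from a grouped-binomial logistic fit
#' with tertile scored 0/1/2.
#'
#' @return list with `or` (named list of [odds_ratio()] results for
#'   `age65plus`, `female`, `cohabiting`, `separated_widowed`,
#'   `schizoaffective`, `bipolar`, `other`) and `deprivation_fit`
#'   (a [fit_logistic()] object).
#' @export
register_reference_stats <- function() {
  sm <- register_counts()$smoking
  cell <- function(fac, cat) {
    r <- sm[sm$factor == fac & sm$category == cat, ]
    c(r$n_current, r$n - r$n_current)
  }
  pool <- function(fac, cats) {
    rs <- sm[sm$factor == fac & sm$category %in% cats, ]
    c(sum(rs$n_current), sum(rs$n) - sum(rs$n_current))
  }
  or2 <- function(exposed, ref) odds_ratio(rbind(exposed, ref))
  ors <- list(
    age65plus = or2(pool("age_band", c("65-74", "75+")),
                    pool("age_band", c("15-24", "25-34", "35-44", "45-54",
                                       "55-64"))),
    female = or2(cell("sex", "female"), cell("sex", "male")),
    cohabiting = or2(cell("marital", "cohabiting"),
                     cell("marital", "single")),
    separated_widowed = or2(cell("marital", "separated_widowed"),
                            cell("marital", "single")),
    schizoaffective = or2(cell("diagnosis", "schizoaffective"),
                          cell("diagnosis", "schizophrenia")),
    bipolar = or2(cell("diagnosis", "bipolar"),
                  cell("diagnosis", "schizophrenia")),
    other = or2(cell("diagnosis", "other"),
                cell("diagnosis", "schizophrenia")))
  dep <- sm[sm$factor == "deprivation", ]
  dep_df <- data.frame(successes = dep$n_current,
                       failures = dep$n - dep$n_current,
                       score = seq_len(nrow(dep)) - 1)
  fit <- fit_logistic(cbind(successes, failures) ~ score, dep_df)
  list(or = ors, deprivation_fit = fit)
}
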
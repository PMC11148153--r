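#' Population parameters for viable-egg accounting
#'
#' Demographic constants used to convert trap counts into egg estimates:
#' the proportion of the wild run that is female and the average fecundity
#' per female. Defaults are the values reported for the Cheboygan River
#' system populations (50% female, 51,000 eggs per female, observed range
#' 3,100-72,000). The fecundity range is consumed only by the synthetic
#' generator's fecundity distribution.
#'
#' @param p_female proportion of wild adults that are female, in \[0, 1\].
#' @param mean_fecundity mean eggs per female.
#' @param fecundity_range length-2 numeric, minimum and maximum eggs per
#'   female; must bracket `mean_fecundity`.
#' @return an object of class `population_params`.
#' @examples
#' population_params()
#' @export
population_params <- function(p_female = 0.5,
                              mean_fecundity = 51000,
                              fecundity_range = c(3100, 72000)) {
  if (!is.numeric(p_female) || length(p_female) != 1 ||
      is.na(p_female) || p_female < 0 || p_female > 1) {
    smr_stop("p_female must be a single number in [0, 1]")
  }
  if (!is.numeric(mean_fecundity) || length(mean_fecundity) != 1 ||
      is.na(mean_fecundity) || mean_fecundity < 0) {
    smr_stop("mean_fecundity must be a single non-negative number")
  }
  if (!is.numeric(fecundity_range) || length(fecundity_range) != 2 ||
      anyNA(fecundity_range) || fecundity_range[1] > fecundity_range[2]) {
    smr_stop("fecundity_range must be a non-decreasing pair (min, max)")
  }
  if (mean_fecundity < fecundity_range[1] || mean_fecundity > fecundity_range[2]) {
    smr_stop("mean_fecundity must lie inside fecundity_range")
  }
  structure(list(p_female = p_female,
                 mean_fecundity = mean_fecundity,
                 fecundity_range = fecundity_range),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population parameters: ",
      sprintf("%.0f%% female, mean fecundity %s eggs (range %s-%s)\n",
              100 * x$p_female,
              format(x$mean_fecundity, big.mark = ","),
              format(x$fecundity_range[1], big.mark = ","),
              format(x$fecundity_range[2], big.mark = ",")))
  invisible(x)
}

#' Validate a table of trap seasons
#'
#' A trap season is one stream-year of the adult assessment: `sterile_released`
#' sterile males released (M), `sterile_recaptured` of them recaptured in the
#' assessment traps (R), `wild_captured` wild (non-sterilized) sea lamprey of
#' both sexes captured (C), and optionally `wild_males_observed` when captured
#' wild animals were sexed. Two further optional columns carry published-table
#' context: `abundance_override`, an externally derived abundance estimate used
#' when the Petersen estimate is unavailable (no-release years) or superseded
#' by an independent estimate, and `ratio_censored_at`, the bound at which a
#' reported overflooding ratio was right-censored (e.g. 40 for ">40:1").
#' An `ambiguous` logical column may flag rows whose published arithmetic is
#' internally inconsistent; it is carried through untouched.
#'
#' @param df data.frame with at least columns `stream`, `year`,
#'   `sterile_released`, `sterile_recaptured`, `wild_captured`.
#' @return the validated data.frame with optional columns filled with NA,
#'   classed `trap_seasons`.
#' @seealso [read_trap_seasons()], [assess_table()]
#' @export
as_trap_seasons <- function(df) {
  req <- c("stream", "year", "sterile_released", "sterile_recaptured",
           "wild_captured")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    smr_stop("trap seasons missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (opt in c("wild_males_observed", "abundance_override", "ratio_censored_at")) {
    if (is.null(df[[opt]])) df[[opt]] <- rep(NA_real_, nrow(df))
    df[[opt]] <- as.numeric(df[[opt]])
  }
  if (is.null(df$ambiguous)) df$ambiguous <- rep(FALSE, nrow(df))
  df$ambiguous <- !is.na(df$ambiguous) & as.logical(df$ambiguous)

  if (anyDuplicated(df[c("stream", "year")])) {
    dup <- df[duplicated(df[c("stream", "year")]), c("stream", "year")]
    smr_stop("duplicate stream-year key(s): ",
             paste(dup$stream, dup$year, sep = "/", collapse = ", "))
  }
  for (col in c("sterile_released", "wild_captured")) {
    if (!all(is_count(df[[col]]))) {
      smr_stop(col, " must be non-negative integer counts")
    }
  }
  # recaptures may be NA in no-release years (published tables print NA)
  r <- df$sterile_recaptured
  if (!all(is.na(r) | is_count(r))) {
    smr_stop("sterile_recaptured must be non-negative integer counts or NA")
  }
  bad <- !is.na(r) & r > df$sterile_released
  if (any(bad)) {
    smr_stop("sterile_recaptured exceeds sterile_released for ",
             paste(df$stream[bad], df$year[bad], sep = "/", collapse = ", "))
  }
  m <- df$wild_males_observed
  bad <- !is.na(m) & (m < 0 | m > df$wild_captured)
  if (any(bad)) {
    smr_stop("wild_males_observed must be between 0 and wild_captured")
  }
  class(df) <- c("trap_seasons", "data.frame")
  df
}

#' Read trap seasons from CSV
#'
#' Expects a UTF-8 CSV with header row and at least the columns documented in
#' [as_trap_seasons()]; blank cells become NA. Extra columns are preserved.
#'
#' @param path path to a CSV file.
#' @return a validated `trap_seasons` data.frame.
#' @export
read_trap_seasons <- function(path) {
  if (!file.exists(path)) smr_stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("NA", ""))
  as_trap_seasons(df)
}

#' Lincoln-Petersen abundance from sterile-male recaptures
#'
#' Sterile males act as the marked cohort: with M released, R recaptured and C
#' wild animals captured under equal catchability, the wild abundance estimate
#' is N-hat = C * M / R, reported rounded half away from zero. Rows where the
#' recapture rate is undefined (M = 0 or R = 0, including NA recaptures) are
#' not estimable and return NA rather than zero.
#'
#' @param sterile_released count of sterile males released (M).
#' @param sterile_recaptured count of those recaptured (R); NA allowed.
#' @param wild_captured count of wild animals captured (C).
#' @return integer vector of abundance estimates, NA where not estimable.
#' @examples
#' petersen_abundance(1400, 70, 3)   # 60
#' petersen_abundance(1350, 257, 1)  # 5
#' @export
petersen_abundance <- function(sterile_released, sterile_recaptured,
                               wild_captured) {
  n <- max(length(sterile_released), length(sterile_recaptured),
           length(wild_captured))
  M <- rep_len(sterile_released, n)
  R <- rep_len(sterile_recaptured, n)
  C <- rep_len(wild_captured, n)
  if (!all(is_count(M)) || !all(is_count(C)) || !all(is.na(R) | is_count(R))) {
    smr_stop("counts must be non-negative integers")
  }
  if (any(!is.na(R) & R > M)) {
    smr_stop("sterile_recaptured exceeds sterile_released")
  }
  est <- ifelse(is.na(R) | R == 0 | M == 0, NA_real_,
                round_half_away(C * M / pmax(R, 1)))
  as.integer(est)
}

#' Realized sterile:wild-male ratio
#'
#' The overflooding ratio realized in the assessment traps: sterile-male
#' recaptures R divided by the wild-male count m. When wild captures were
#' sexed, m is the observed male count; otherwise m = C * (1 - p_female),
#' the expected male fraction of the wild catch. Returns the exact real
#' ratio; published tables report `round_half_away()` of it. By convention
#' the ratio is 0 when R = 0 (no-release years print "0:1") and Inf when
#' R > 0 but no wild males were available as denominator.
#'
#' @param sterile_recaptured sterile males recaptured (R).
#' @param wild_captured wild captures of both sexes (C).
#' @param wild_males_observed optional sexed male count; NA to use the
#'   expected fraction of `wild_captured`.
#' @param pop a [population_params()] object supplying `p_female`.
#' @return numeric vector of exact ratios (possibly Inf).
#' @examples
#' sterile_wild_male_ratio(28, 9)                       # 6.22 -> reported 6:1
#' sterile_wild_male_ratio(70, 3, wild_males_observed = 2)  # 35
#' @export
sterile_wild_male_ratio <- function(sterile_recaptured, wild_captured,
                                    wild_males_observed = NA,
                                    pop = population_params()) {
  n <- max(length(sterile_recaptured), length(wild_captured),
           length(wild_males_observed))
  R <- rep_len(sterile_recaptured, n)
  C <- rep_len(wild_captured, n)
  m_obs <- rep_len(wild_males_observed, n)
  R[is.na(R)] <- 0
  m <- ifelse(is.na(m_obs), C * (1 - pop$p_female), m_obs)
  ifelse(R == 0, 0, ifelse(m == 0, Inf, R / m))
}

#' Viable eggs deposited before sterile-male release
#'
#' Expected fertilizable eggs from the estimated wild run: abundance times
#' the female proportion times mean fecundity, rounded half away from zero.
#'
#' @param abundance estimated wild abundance (integer-valued; NA propagates).
#' @param pop a [population_params()] object.
#' @return numeric vector of egg counts.
#' @examples
#' viable_eggs_before(21)  # 535,500
#' @export
viable_eggs_before <- function(abundance, pop = population_params()) {
  if (any(!is.na(abundance) & abundance < 0)) {
    smr_stop("abundance must be non-negative")
  }
  round_half_away(abundance * pop$p_female * pop$mean_fecundity)
}

#' Viable eggs remaining after sterile-male release
#'
#' Discounts the pre-release egg estimate by the realized sterile:wild-male
#' ratio r, assuming every egg could be fertilized by a different male and
#' mating is random with respect to sterility. Two conventions are offered:
#'
#' * `"table"` (default): eggs_after = eggs_before / r, the accounting used
#'   in the published assessment tables (a wild male is outnumbered r:1, so
#'   a fraction 1/r of eggs meet a fertile male).
#' * `"random-mating"`: eggs_after = eggs_before / (r + 1), the standard
#'   competing-males form in which wild males are 1 of r + 1 candidates.
#'
#' A ratio of 0 (no sterile males) leaves the egg count unchanged under both
#' conventions; an infinite ratio drives it to 0.
#'
#' @param eggs_before pre-release viable egg estimate.
#' @param ratio realized sterile:wild-male ratio (>= 0; Inf allowed).
#' @param convention `"table"` or `"random-mating"`.
#' @return numeric vector of post-release egg counts, rounded half away from
#'   zero.
#' @examples
#' viable_eggs_after(2295000, 6)    # 382,500
#' viable_eggs_after(127500, 514)   # 248
#' @export
viable_eggs_after <- function(eggs_before, ratio,
                              convention = c("table", "random-mating")) {
  convention <- match.arg(convention)
  if (any(!is.na(eggs_before) & eggs_before < 0)) {
    smr_stop("eggs_before must be non-negative")
  }
  if (any(!is.na(ratio) & ratio < 0)) smr_stop("ratio must be non-negative")
  div <- if (convention == "table") ratio else ratio + 1
  out <- ifelse(!is.na(ratio) & ratio == 0, eggs_before,
                round_half_away(eggs_before / div))
  ifelse(is.infinite(ratio), 0, out)
}

#' Percent reduction in viable eggs implied by an overflooding ratio
#'
#' Under the table convention, eggs after release are eggs_before / r, so the
#' reduction is 100 * (1 - 1/r): monotone in r, 0 at r = 1 and approaching
#' (never reaching) 100 as r grows.
#'
#' @param ratio realized sterile:wild-male ratio, >= 1.
#' @return percent reduction in \[0, 100).
#' @examples
#' egg_reduction_percent(6)    # 83.33
#' egg_reduction_percent(100)  # 99
#' @export
egg_reduction_percent <- function(ratio) {
  if (any(!is.na(ratio) & ratio < 1)) {
    smr_stop("egg_reduction_percent requires ratio >= 1 under the table convention")
  }
  100 * (1 - 1 / ratio)
}

#' Batch adult assessment (published-table reproduction)
#'
#' Runs the full adult assessment chain over a table of trap seasons:
#' Petersen abundance (or the row's `abundance_override` when the Petersen
#' estimate is unavailable or superseded), realized sterile:wild-male ratio
#' (reported as a rounded integer, right-censored where `ratio_censored_at`
#' is set), and viable eggs before/after release with the implied percent
#' reduction. NA propagation mirrors the published accounting: rows with no
#' wild captures or no recaptures (and no override) are not estimable and
#' report NA, never zero.
#'
#' @param seasons a `trap_seasons` data.frame (see [as_trap_seasons()]).
#' @param pop a [population_params()] object.
#' @param convention egg-discount convention passed to [viable_eggs_after()].
#' @return a data.frame classed `smr_assessment` with one row per season:
#'   `stream`, `year`, `sterile_released`, `abundance_wild`,
#'   `ratio_sterile_to_wild_male` (reported integer), `ratio_exact`,
#'   `ratio_censored`, `eggs_before`, `eggs_after`, `egg_reduction_pct`,
#'   `ambiguous`.
#' @examples
#' seasons <- as_trap_seasons(data.frame(
#'   stream = "Sturgeon", year = 2022, sterile_released = 1400,
#'   sterile_recaptured = 70, wild_captured = 3, wild_males_observed = 2))
#' assess_table(seasons)
#' @export
assess_table <- function(seasons, pop = population_params(),
                         convention = c("table", "random-mating")) {
  convention <- match.arg(convention)
  seasons <- as_trap_seasons(seasons)
  n <- nrow(seasons)
  if (n == 0) {
    out <- data.frame(stream = character(), year = integer(),
                      sterile_released = integer(), abundance_wild = integer(),
                      ratio_sterile_to_wild_male = numeric(),
                      ratio_exact = numeric(), ratio_censored = logical(),
                      eggs_before = numeric(), eggs_after = numeric(),
                      egg_reduction_pct = numeric(), ambiguous = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("smr_assessment", "data.frame")
    return(out)
  }

  petersen <- petersen_abundance(seasons$sterile_released,
                                 seasons$sterile_recaptured,
                                 seasons$wild_captured)
  # no wild captures -> the estimator degenerates to 0; treat as not estimable
  petersen[seasons$wild_captured == 0] <- NA_integer_
  abundance <- ifelse(is.na(seasons$abundance_override), petersen,
                      seasons$abundance_override)

  r_exact <- sterile_wild_male_ratio(seasons$sterile_recaptured,
                                     seasons$wild_captured,
                                     seasons$wild_males_observed, pop)
  censor <- seasons$ratio_censored_at
  censored <- !is.na(censor) & r_exact > censor
  r_rep <- ifelse(censored, censor, round_half_away(r_exact))
  # releases with no usable denominator and no censoring bound: ratio unknown
  r_rep[is.infinite(r_rep)] <- NA_real_

  eggs_before <- viable_eggs_before(abundance, pop)
  eggs_after <- ifelse(is.na(r_rep), NA_real_,
                       viable_eggs_after(eggs_before, r_rep, convention))
  reduction <- ifelse(!is.na(eggs_before) & eggs_before > 0,
                      100 * (1 - eggs_after / eggs_before), NA_real_)

  out <- data.frame(stream = seasons$stream, year = seasons$year,
                    sterile_released = seasons$sterile_released,
                    abundance_wild = as.integer(abundance),
                    ratio_sterile_to_wild_male = r_rep,
                    ratio_exact = r_exact,
                    ratio_censored = censored,
                    eggs_before = eggs_before, eggs_after = eggs_after,
                    egg_reduction_pct = reduction,
                    ambiguous = seasons$ambiguous,
                    stringsAsFactors = FALSE)
  class(out) <- c("smr_assessment", "data.frame")
  out
}

#' Write an assessment table to CSV
#'
#' NA markers are rendered as empty cells so the file mirrors published
#' tables' blank entries.
#'
#' @param x an `smr_assessment` data.frame from [assess_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assessment <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}
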
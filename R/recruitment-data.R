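#' Length-by-month age-1 assignment for larval sea lamprey
#'
#' Larvae are assigned to the age-1 class (spawned the previous calendar
#' year) from total length and capture month, using the seasonal growth
#' bands: 20-40 mm in May-June, 40-60 mm in July-August, 60-80 mm in
#' September-October. Captures outside May-October cannot be assessed with
#' this rule and return FALSE, with the returned vector carrying a logical
#' `assessable` attribute distinguishing "out of band" from "rule does not
#' apply".
#'
#' @param length_mm larval total length in mm (> 0).
#' @param month capture month, integer 1-12.
#' @return logical vector, TRUE where the larva classifies as age-1;
#'   attribute `assessable` is FALSE for months outside May-October.
#' @examples
#' assign_age1(30, 6)   # TRUE
#' assign_age1(50, 5)   # FALSE: 50 mm is outside the May-June band
#' assign_age1(70, 9)   # TRUE
#' @export
assign_age1 <- function(length_mm, month) {
  n <- max(length(length_mm), length(month))
  L <- rep_len(length_mm, n)
  mo <- rep_len(month, n)
  if (any(!is.na(L) & L <= 0)) smr_stop("length_mm must be positive")
  if (any(!is.na(mo) & !(mo %in% 1:12))) smr_stop("month must be in 1..12")
  lo <- c(NA, NA, NA, NA, 20, 20, 40, 40, 60, 60, NA, NA)[mo]
  hi <- c(NA, NA, NA, NA, 40, 40, 60, 60, 80, 80, NA, NA)[mo]
  assessable <- !is.na(lo)
  out <- assessable & !is.na(L) & L >= lo & L <= hi
  attr(out, "assessable") <- assessable
  out
}

#' Read larval survey records from CSV
#'
#' Two dialects are accepted. Density records carry one row per survey site
#' with columns `stream`, `year`, `month`, `site`, `density_per_m2`. Length
#' records carry one row per captured larva with columns `stream`, `year`,
#' `month`, `site`, `length_mm`, `area_m2` (area electrofished at the site);
#' they are aged via [assign_age1()] and aggregated to an age-1 density per
#' site (age-1 count / area). Rows from months where the aging rule does not
#' apply are dropped with a warning.
#'
#' @param path path to a CSV file.
#' @return data.frame with columns `stream`, `year`, `month`, `site`,
#'   `density_per_m2`.
#' @export
read_larval_surveys <- function(path) {
  if (!file.exists(path)) smr_stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("NA", ""))
  req <- c("stream", "year", "month", "site")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    smr_stop("larval surveys missing column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  if (!is.null(df$density_per_m2)) {
    return(df[c(req, "density_per_m2")])
  }
  if (is.null(df$length_mm) || is.null(df$area_m2)) {
    smr_stop("larval surveys need either density_per_m2 or length_mm + area_m2")
  }
  age1 <- assign_age1(df$length_mm, df$month)
  assessable <- attr(age1, "assessable")
  if (any(!assessable)) {
    warning(sum(!assessable), " larval record(s) outside May-October dropped: ",
            "age-1 rule not assessable", call. = FALSE)
    df <- df[assessable, , drop = FALSE]
    age1 <- age1[assessable]
  }
  key <- interaction(df$stream, df$year, df$month, df$site, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(df)), key), function(i) {
    area <- unique(df$area_m2[i])
    if (length(area) != 1) {
      smr_stop("inconsistent area_m2 within a survey site record")
    }
    data.frame(stream = df$stream[i][1], year = df$year[i][1],
               month = df$month[i][1], site = df$site[i][1],
               density_per_m2 = sum(age1[i]) / area,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

#' Read the sterile-male release table from CSV
#'
#' @param path CSV with columns `stream`, `spawning_year`, `sterile_released`.
#' @return validated data.frame of releases.
#' @export
read_releases <- function(path) {
  if (!file.exists(path)) smr_stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("NA", ""))
  req <- c("stream", "spawning_year", "sterile_released")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    smr_stop("releases missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is_count(df$sterile_released))) {
    smr_stop("sterile_released must be non-negative integer counts")
  }
  if (anyDuplicated(df[c("stream", "spawning_year")])) {
    smr_stop("duplicate stream/spawning_year in releases")
  }
  df
}

#' Assemble a recruitment dataset for model fitting
#'
#' Joins age-1 survey densities to release effort and builds the model's
#' observation index. The recruitment index is `round_half_away(density *
#' 1000)`; zero-density surveys are legitimate observations and are kept.
#' Effort is aligned by life history: an age-1 larva surveyed in year t was
#' spawned in year t - 1, so its effort is E = sterile_released(t - 1) / 1000.
#' Observations in survey years whose spawning-year release count is unknown
#' are dropped with a warning.
#'
#' @param surveys data.frame of survey densities (see [read_larval_surveys()]).
#' @param releases data.frame of releases (see [read_releases()]).
#' @return an object of class `smr_recruitment_data`: a list with `obs`
#'   (stream, year, site, density, index, effort), `streams` (level order),
#'   and `groups` (one row per stream-year with its effort and observation
#'   count).
#' @export
recruitment_data <- function(surveys, releases) {
  req <- c("stream", "year", "site", "density_per_m2")
  missing_cols <- setdiff(req, names(surveys))
  if (length(missing_cols)) {
    smr_stop("surveys missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(surveys$density_per_m2) | surveys$density_per_m2 < 0)) {
    smr_stop("density_per_m2 must be non-negative and non-missing")
  }
  releases <- releases[c("stream", "spawning_year", "sterile_released")]

  obs <- data.frame(stream = as.character(surveys$stream),
                    year = as.integer(surveys$year),
                    site = as.character(surveys$site),
                    density = surveys$density_per_m2,
                    stringsAsFactors = FALSE)
  obs$index <- as.integer(round_half_away(obs$density * 1000))
  key <- paste(obs$stream, obs$year - 1L)
  rel_key <- paste(releases$stream, releases$spawning_year)
  hit <- match(key, rel_key)
  if (anyNA(hit)) {
    dropped <- unique(key[is.na(hit)])
    warning("dropping ", sum(is.na(hit)), " survey observation(s) with no ",
            "release record for the spawning year: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    obs <- obs[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  if (nrow(obs) == 0) smr_stop("no observations left after effort alignment")
  obs$effort <- releases$sterile_released[hit] / 1000

  streams <- sort(unique(obs$stream))
  obs$group <- paste(obs$stream, obs$year)
  gk <- !duplicated(obs$group)
  groups <- data.frame(group = obs$group[gk], stream = obs$stream[gk],
                       year = obs$year[gk], effort = obs$effort[gk],
                       stringsAsFactors = FALSE)
  groups <- groups[order(groups$stream, groups$year), ]
  rownames(groups) <- NULL
  groups$n_obs <- as.integer(table(obs$group)[groups$group])
  structure(list(obs = obs, streams = streams, groups = groups),
            class = "smr_recruitment_data")
}

#' @export
print.smr_recruitment_data <- function(x, ...) {
  cat("Age-1 recruitment dataset:", nrow(x$obs), "survey observations,",
      nrow(x$groups), "stream-years,", length(x$streams), "stream(s)\n")
  cat("Streams:", paste(x$streams, collapse = ", "), "\n")
  invisible(x)
}
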
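#' @title Food-frequency questionnaire conversion
#' @description Tools that turn categorical touchscreen FFQ responses into
#'   quantitative dietary traits: per-item frequency conversion, the milk
#'   volume estimate, food-group composition, and descriptive summaries.
#' @name ffq
NULL

.ffq_env <- new.env(parent = emptyenv())

# Normalise a label for matching: lower case, collapse whitespace, map
# unicode dashes to "-" (biobank exports mix hyphen and en-dash).
.norm_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[‐‑‒–—]", "-", x)
  gsub("[[:space:]]+", " ", x)
}

#' Load the FFQ conversion table
#'
#' Reads the versioned YAML conversion table shipped with the package (or a
#' user-supplied override) and caches it for the session.
#'
#' @param path Optional path to an alternative conversion YAML.
#' @return A list with components `classes`, `milk`, `quantitative_units`
#'   and `missing_labels`.
#' @export
ffq_conversion_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ffq_env$table)) return(.ffq_env$table)
    path <- system.file("extdata", "ffq_conversion.yaml", package = "dietmr")
    tab <- yaml::read_yaml(path)
    .ffq_env$table <- tab
    return(tab)
  }
  yaml::read_yaml(path)
}

.resolve_class <- function(item_class, tab) {
  key <- .norm_label(item_class)
  for (nm in names(tab$classes)) {
    if (key %in% .norm_label(tab$classes[[nm]]$aliases)) return(tab$classes[[nm]])
  }
  stop("unknown FFQ item class: '", item_class, "'", call. = FALSE)
}

#' Convert a categorical FFQ response to a weekly frequency
#'
#' Maps a response label for a frequency-class item (meat, fish, cheese, or
#' alcohol, which has its own label set) to its numeric value in times/week.
#' Labels are matched case-insensitively after whitespace and dash
#' normalisation; "do not know" / "prefer not to answer" return `NA`.
#'
#' @param item_class Item class label: `"meat"`, `"fish"`, `"cheese"` or
#'   `"alcohol"`.
#' @param response Response label(s); vectorised.
#' @param table Conversion table, see [ffq_conversion_table()].
#' @return Numeric vector of frequencies (times/week); `NA` for the declared
#'   missing labels.
#' @examples
#' convert_frequency("meat", "2-4 times a week")   # 3
#' convert_frequency("alcohol", "Special occasions only") # 0.125
#' @export
convert_frequency <- function(item_class, response, table = ffq_conversion_table()) {
  cls <- .resolve_class(item_class, table)
  labels <- .norm_label(vapply(cls$levels, `[[`, "", "label"))
  values <- vapply(cls$levels, function(l) as.numeric(l$value), 0)
  miss <- .norm_label(table$missing_labels)
  key <- .norm_label(response)
  out <- values[match(key, labels)]
  out[key %in% miss] <- NA_real_
  bad <- is.na(out) & !(key %in% miss) & !is.na(response)
  if (any(bad)) {
    stop("unknown response label(s) for item class '", item_class, "': ",
         paste(unique(response[bad]), collapse = ", "), call. = FALSE)
  }
  out[is.na(response)] <- NA_real_
  unname(out)
}

#' Estimate daily milk volume
#'
#' Milk intake (mL/day) is not asked directly; it is reconstructed from the
#' milk type and the number of daily bowls of breakfast cereal and cups of
#' coffee and tea, as 100 x bowls + 25 x coffee cups + 35 x tea cups, and is
#' zero for participants who never or rarely take milk.
#'
#' @param milk_type One of `"never/rarely"`, `"full cream"`,
#'   `"semi-skimmed"`, `"skimmed"` (vectorised; `NA` propagates).
#' @param cereal_bowls,coffee_cups,tea_cups Non-negative daily counts.
#' @return Milk volume in mL/day.
#' @export
estimate_milk <- function(milk_type, cereal_bowls, coffee_cups, tea_cups) {
  tab <- ffq_conversion_table()
  types <- .norm_label(tab$milk$types)
  key <- .norm_label(milk_type)
  unknown <- !is.na(milk_type) & !(key %in% types)
  if (any(unknown)) {
    stop("unknown milk type: ", paste(unique(milk_type[unknown]), collapse = ", "),
         call. = FALSE)
  }
  counts <- cbind(cereal_bowls, coffee_cups, tea_cups)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative", call. = FALSE)
  co <- tab$milk$coefficients
  vol <- co$cereal_bowls * cereal_bowls + co$coffee_cups * coffee_cups +
    co$tea_cups * tea_cups
  vol[key == .norm_label("never/rarely")] <- 0
  vol[is.na(milk_type)] <- NA_real_
  unname(vol)
}

#' Compose food groups from single-item traits
#'
#' Builds the derived quantitative trait table from per-item values:
#' red meat = pork + beef + lamb (times/week), total fish = oily + non-oily
#' (times/week), total fruits = fresh + 1/2 dried (servings/day), total
#' vegetables = cooked + raw (servings/day); processed meat, poultry,
#' cheese, coffee, tea and alcohol pass through; milk is computed from the
#' milk columns when a `milk` column is not already present. A composite is
#' missing iff any constituent is missing.
#'
#' @param items Data frame of per-item numeric values. Recognised columns:
#'   `pork`, `beef`, `lamb`, `processed_meat`, `poultry`, `oily_fish`,
#'   `nonoily_fish`, `cheese`, `fresh_fruit`, `dried_fruit`, `cooked_veg`,
#'   `raw_veg`, `coffee`, `tea`, `alcohol`, and either `milk` (mL/day) or
#'   (`milk_type`, `cereal_bowls`, `coffee_cups`, `tea_cups`).
#' @return A data frame of derived traits with one row per sample; the
#'   per-trait missing counts are attached as attribute `"missing"`.
#' @export
compose_groups <- function(items) {
  stopifnot(is.data.frame(items))
  n <- nrow(items)
  col <- function(nm) if (nm %in% names(items)) items[[nm]] else rep(NA_real_, n)
  out <- data.frame(
    red_meat       = col("pork") + col("beef") + col("lamb"),
    processed_meat = col("processed_meat"),
    poultry        = col("poultry"),
    total_fish     = col("oily_fish") + col("nonoily_fish"),
    milk           = if ("milk" %in% names(items)) items$milk else
      estimate_milk(col("milk_type"), col("cereal_bowls"),
                    col("coffee_cups"), col("tea_cups")),
    cheese         = col("cheese"),
    total_fruits   = col("fresh_fruit") + 0.5 * col("dried_fruit"),
    total_veg      = col("cooked_veg") + col("raw_veg"),
    coffee         = col("coffee"),
    tea            = col("tea"),
    alcohol        = col("alcohol")
  )
  if (!is.null(rownames(items))) rownames(out) <- rownames(items)
  miss <- vapply(out, function(x) sum(is.na(x)), 0L)
  attr(out, "missing") <- data.frame(trait = names(miss), n_missing = unname(miss),
                                     pct_missing = unname(100 * miss / n))
  out
}

#' Descriptive summary of derived diet traits
#'
#' For each trait, runs a Shapiro-Wilk normality test (on a random subsample
#' capped at `max_sw` observations, since the test is undefined above 5000
#' and over-powered at biobank scale) and reports mean +/- sd when normality
#' is not rejected at `alpha`, otherwise median and interquartile range,
#' together with missingness.
#'
#' @param traits Data frame of numeric traits (see [compose_groups()]).
#' @param max_sw Cap on the Shapiro-Wilk subsample size (default 5000).
#' @param alpha Normality rejection level (default 0.05).
#' @param seed Seed for the subsample draw, recorded in the output.
#' @return Data frame with one row per trait: n, n_missing, pct_missing,
#'   shapiro_p, location, spread, and the summary type used.
#' @export
summarize_traits <- function(traits, max_sw = 5000, alpha = 0.05, seed = 1L) {
  stopifnot(is.data.frame(traits))
  rows <- lapply(names(traits), function(nm) {
    x <- traits[[nm]]
    ok <- x[!is.na(x)]
    if (length(ok) == 0) stop("trait '", nm, "' is entirely missing", call. = FALSE)
    if (length(ok) < 3) stop("trait '", nm, "' has fewer than 3 non-missing values",
                             call. = FALSE)
    if (stats::sd(ok) == 0) stop("trait '", nm, "' is constant (zero variance)",
                                 call. = FALSE)
    sub <- ok
    if (length(sub) > max_sw) {
      set.seed(seed)
      sub <- sample(sub, max_sw)
    }
    sw <- stats::shapiro.test(sub)$p.value
    if (sw < alpha) {
      q <- stats::quantile(ok, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(trait = nm, n = length(ok), n_missing = sum(is.na(x)),
                 pct_missing = 100 * mean(is.na(x)), shapiro_p = sw,
                 summary = "median (Q1-Q3)", location = q[2],
                 spread_low = q[1], spread_high = q[3])
    } else {
      m <- mean(ok); s <- stats::sd(ok)
      data.frame(trait = nm, n = length(ok), n_missing = sum(is.na(x)),
                 pct_missing = 100 * mean(is.na(x)), shapiro_p = sw,
                 summary = "mean +/- sd", location = m,
                 spread_low = m - s, spread_high = m + s)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "shapiro_subsample_seed") <- seed
  out
}
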
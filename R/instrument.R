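#' Define an ordinal questionnaire instrument
#'
#' An instrument specification maps questionnaire items to latent factors,
#' records which items are reverse-keyed, names the marker item whose loading
#' is fixed at 1 to set each factor's scale, and fixes the number of ordinal
#' response categories shared by all items.
#'
#' @param items data frame with columns `item` (unique machine key), `factor`
#'   (factor key the item belongs to), and optionally `reversed` (logical,
#'   default `FALSE`) and `label` (display label, default the item key).
#' @param factors optional data frame with columns `factor` and optionally
#'   `marker` (item key whose loading is fixed at 1; default the first item
#'   listed for the factor) and `label`. When omitted, factors are taken in
#'   order of first appearance in `items` with default markers.
#' @param n_categories number of ordinal response levels (>= 2), global to
#'   the instrument.
#'
#' @return An object of class `"instrument"`: a list with elements `items`
#'   (data frame: item, label, factor, reversed), `factors` (data frame:
#'   factor, label, marker) and `n_categories`.
#'
#' @examples
#' spec <- instrument(data.frame(
#'   item = c("calm", "tense", "rested", "tired"),
#'   factor = c("mood", "mood", "energy", "energy"),
#'   reversed = c(FALSE, TRUE, FALSE, TRUE)))
#' n_items(spec)
#' @export
instrument <- function(items, factors = NULL, n_categories = 5L) {
  stopifnot(is.data.frame(items), all(c("item", "factor") %in% names(items)))
  items <- data.frame(
    item = as.character(items$item),
    label = if ("label" %in% names(items)) as.character(items$label) else as.character(items$item),
    factor = as.character(items$factor),
    reversed = if ("reversed" %in% names(items)) as.logical(items$reversed) else FALSE,
    stringsAsFactors = FALSE
  )
  fkeys <- unique(items$factor)
  if (is.null(factors)) {
    factors <- data.frame(factor = fkeys, stringsAsFactors = FALSE)
  }
  factors <- data.frame(
    factor = as.character(factors$factor),
    label = if ("label" %in% names(factors)) as.character(factors$label) else as.character(factors$factor),
    marker = if ("marker" %in% names(factors)) as.character(factors$marker) else NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(factors))) {
    if (is.na(factors$marker[i])) {
      factors$marker[i] <- items$item[items$factor == factors$factor[i]][1]
    }
  }
  x <- structure(
    list(items = items, factors = factors, n_categories = as.integer(n_categories)),
    class = "instrument"
  )
  validate_instrument(x)
  x
}

#' Validate an instrument specification
#'
#' Checks the structural invariants: unique item keys (every item belongs to
#' exactly one factor), at least two items per factor, markers that are
#' members of their own factor, and at least two response categories.
#'
#' @param x an `"instrument"` object.
#' @return `x`, invisibly; otherwise an error naming the offending field.
#' @export
validate_instrument <- function(x) {
  stopifnot(inherits(x, "instrument"))
  if (anyDuplicated(x$items$item)) {
    stop("duplicate item key(s): ",
         paste(unique(x$items$item[duplicated(x$items$item)]), collapse = ", "),
         " (every item must belong to exactly one factor)")
  }
  if (anyDuplicated(x$factors$factor)) {
    stop("duplicate factor key(s): ",
         paste(unique(x$factors$factor[duplicated(x$factors$factor)]), collapse = ", "))
  }
  if (!all(x$items$factor %in% x$factors$factor)) {
    bad <- setdiff(unique(x$items$factor), x$factors$factor)
    stop("item(s) assigned to unknown factor(s): ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(x$items$factor, levels = x$factors$factor))
  if (any(counts < 2)) {
    stop("factor(s) with fewer than 2 items: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  for (i in seq_len(nrow(x$factors))) {
    own <- x$items$item[x$items$factor == x$factors$factor[i]]
    if (!(x$factors$marker[i] %in% own)) {
      stop("marker item '", x$factors$marker[i], "' is not a member of factor '",
           x$factors$factor[i], "'")
    }
  }
  if (is.na(x$n_categories) || x$n_categories < 2L) {
    stop("n_categories must be an integer >= 2")
  }
  invisible(x)
}

#' @export
print.instrument <- function(x, ...) {
  cat(sprintf("<instrument> %d factors, %d items, %d response categories\n",
              n_factors(x), n_items(x), x$n_categories))
  for (i in seq_len(nrow(x$factors))) {
    f <- x$factors$factor[i]
    it <- x$items[x$items$factor == f, ]
    tags <- ifelse(it$reversed, " (reversed)", "")
    tags[it$item == x$factors$marker[i]] <- paste0(tags[it$item == x$factors$marker[i]], " [marker]")
    cat(sprintf("  %s: %s\n", x$factors$label[i],
                paste0(it$item, tags, collapse = ", ")))
  }
  invisible(x)
}

#' Number of items / factors in an instrument
#' @param x an `"instrument"` object.
#' @return integer count.
#' @export
n_items <- function(x) nrow(x$items)

#' @rdname n_items
#' @export
n_factors <- function(x) nrow(x$factors)

#' Item-to-factor index map
#'
#' @param x an `"instrument"` object.
#' @return integer vector of length `n_items(x)`, named by item key, giving
#'   the index (into `x$factors`) of the factor each item loads on.
#' @export
item_factor_index <- function(x) {
  idx <- match(x$items$factor, x$factors$factor)
  names(idx) <- x$items$item
  idx
}

#' Marker-item indicator
#'
#' @param x an `"instrument"` object.
#' @return named logical vector over items; `TRUE` where the item is its
#'   factor's marker (loading fixed at 1).
#' @export
is_marker <- function(x) {
  m <- x$items$item %in% x$factors$marker
  names(m) <- x$items$item
  m
}

#' Reverse-code an ordinal response
#'
#' Maps category `r` to `n_categories + 1 - r` so that, after recoding,
#' higher always means more of the measured construct. Missing values pass
#' through. Reversal is an involution: applying it twice restores the raw
#' response.
#'
#' @param response vector of ordinal categories (integers in
#'   `1:n_categories`), `NA` allowed.
#' @param n_categories number of response levels.
#' @return recoded vector of the same length.
#' @examples
#' reverse_code(c(1, 3, 5, NA), 5)  # 5 3 1 NA
#' @export
reverse_code <- function(response, n_categories) {
  ok <- is.na(response) | (response >= 1 & response <= n_categories)
  if (!all(ok)) {
    stop("response categories out of range 1..", n_categories, ": ",
         paste(utils::head(response[!ok], 5), collapse = ", "))
  }
  n_categories + 1 - response
}

#' The built-in HCFC-8 caregiver instrument
#'
#' The 20-item, 8-factor Health Capability of Family Caregivers instrument:
#' psychological functioning (3 items), physical functioning (2, both
#' reversed), self-efficacy towards health services (2), lifestyle value (3),
#' family support (3, two reversed), social capital (3), material
#' conditions/security (2) and quality of information and healthcare
#' services (2), each item on a 5-point Likert scale. Higher recoded scores
#' mean better health capability. The physical-functioning marker is
#' "health got worse" (its loading is the fixed 1); the other factors use
#' their first-listed item as marker.
#'
#' @return an `"instrument"` object with 8 factors, 20 items, 5 categories.
#' @examples
#' hcfc8_instrument()
#' @export
hcfc8_instrument <- function() {
  items <- data.frame(
    item = c(
      "self_esteem", "body_image", "negative_affects",
      "feeling_tired", "health_got_worse",
      "confidence_contact", "ability_information",
      "want_to_care", "enjoy_caring", "caring_feels_good",
      "difficulty_help", "feeling_abandoned", "family_works_together",
      "personal_relationships", "sexual_activity", "social_support",
      "financial_resources", "safety_security",
      "help_received", "availability_information"
    ),
    label = c(
      "Self-esteem", "Body image", "Negative affects",
      "Feeling tired", "Health got worse",
      "Confidence to know who to contact", "Ability to get information",
      "Want to care", "Enjoy caring", "Caring makes one feel good",
      "Difficulty getting help", "Feeling abandoned", "Family works together",
      "Personal relationships", "Sexual activity", "Social support",
      "Financial resources", "Freedom and physical safety and security",
      "Help received", "Availability of information"
    ),
    factor = rep(c("psychological", "physical", "self_efficacy", "lifestyle",
                   "family_support", "social_capital", "material_security",
                   "health_services"),
                 times = c(3, 2, 2, 3, 3, 3, 2, 2)),
    reversed = c(
      FALSE, FALSE, TRUE,
      TRUE, TRUE,
      FALSE, FALSE,
      FALSE, FALSE, FALSE,
      TRUE, TRUE, FALSE,
      FALSE, FALSE, FALSE,
      FALSE, FALSE,
      FALSE, FALSE
    ),
    stringsAsFactors = FALSE
  )
  factors <- data.frame(
    factor = c("psychological", "physical", "self_efficacy", "lifestyle",
               "family_support", "social_capital", "material_security",
               "health_services"),
    label = c("Psychological functioning", "Physical functioning",
              "Self-efficacy towards health services", "Lifestyle value",
              "Family support", "Social capital",
              "Material conditions / security",
              "Quality of information and healthcare services"),
    marker = c("self_esteem", "health_got_worse", "confidence_contact",
               "want_to_care", "difficulty_help", "personal_relationships",
               "financial_resources", "help_received"),
    stringsAsFactors = FALSE
  )
  instrument(items, factors, n_categories = 5L)
}

#' Read / write an instrument specification file
#'
#' Instruments are serialized as YAML with top-level keys `n_categories` and
#' `factors`; each factor has `name`, `label`, `marker` and a list of
#' `items`, each with `name`, `label` and `reversed`. A copy of the HCFC-8
#' instrument ships as `system.file("extdata", "hcfc8.instrument",
#' package = "ordcfa")`. `read_instrument(write_instrument(spec, path))`
#' round-trips to an identical specification.
#'
#' @param path file path.
#' @param spec an `"instrument"` object.
#' @return `read_instrument` returns an `"instrument"`; `write_instrument`
#'   returns `path` invisibly.
#' @export
read_instrument <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed instrument file '", path, "': ",
                                           conditionMessage(e)))
  if (is.null(doc$factors) || length(doc$factors) == 0) {
    stop("instrument file '", path, "': no factors defined")
  }
  rows <- list(); frows <- list()
  for (f in doc$factors) {
    if (is.null(f$name)) stop("instrument file '", path, "': factor without a name")
    if (is.null(f$items) || length(f$items) == 0) {
      stop("instrument file '", path, "': factor '", f$name, "' has no items")
    }
    for (it in f$items) {
      if (is.null(it$name)) stop("factor '", f$name, "' has an item without a name")
      rows[[length(rows) + 1L]] <- data.frame(
        item = it$name,
        label = if (is.null(it$label)) it$name else it$label,
        factor = f$name,
        reversed = isTRUE(it$reversed),
        stringsAsFactors = FALSE
      )
    }
    frows[[length(frows) + 1L]] <- data.frame(
      factor = f$name,
      label = if (is.null(f$label)) f$name else f$label,
      marker = if (is.null(f$marker)) NA_character_ else f$marker,
      stringsAsFactors = FALSE
    )
  }
  instrument(do.call(rbind, rows), do.call(rbind, frows),
             n_categories = if (is.null(doc$n_categories)) 5L else doc$n_categories)
}

#' @rdname read_instrument
#' @export
write_instrument <- function(spec, path) {
  validate_instrument(spec)
  doc <- list(
    n_categories = spec$n_categories,
    factors = lapply(seq_len(nrow(spec$factors)), function(i) {
      f <- spec$factors[i, ]
      it <- spec$items[spec$items$factor == f$factor, ]
      list(
        name = f$factor, label = f$label, marker = f$marker,
        items = lapply(seq_len(nrow(it)), function(j) {
          list(name = it$item[j], label = it$label[j], reversed = it$reversed[j])
        })
      )
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
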
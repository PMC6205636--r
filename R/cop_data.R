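# Reading, validation and canonicalization of the five input tables.
#
# Input dialect is a fixed documented CSV schema (UTF-8, comma-separated,
# quoted fields allowed). The source COP documents themselves are never
# parsed; this package consumes pre-extracted tables.

cop_table_kinds <- c("funding", "subawards", "crosscutting", "classes", "rates")

crosscutting_categories <- c(
  "CONSTRUCTION", "RENOVATION", "CONSTRUCTION_RENOVATION",
  "MOTOR_VEHICLES_PURCHASED"
)

partner_classes <- c("IO", "UNIVERSITY", "LOCAL", "USG", "NA")

#' Column schema for one of the five input tables
#'
#' @param kind One of `"funding"`, `"subawards"`, `"crosscutting"`,
#'   `"classes"`, `"rates"`.
#' @return Character vector of required column names, in canonical order.
#' @export
cop_schema <- function(kind) {
  kind <- match.arg(kind, cop_table_kinds)
  switch(kind,
    funding      = c("country", "year", "mechanism_id", "partner", "org_type",
                     "agency", "budget_code", "amount"),
    subawards    = c("prime_partner", "agency", "year", "sub_partner",
                     "amount"),
    crosscutting = c("mechanism_id", "partner", "agency", "year", "category",
                     "amount"),
    classes      = c("partner", "class"),
    rates        = c("partner", "period_start", "period_end",
                     "on_campus_osa", "off_campus_osa")
  )
}

#' Default suffix tokens stripped by name canonicalization
#'
#' Corporate suffixes that recur as spelling variants of the same partner
#' across ledger years. Editable: pass your own list to [normalize_name()]
#' or [read_cop_table()].
#'
#' @return Character vector of lower-case suffix tokens.
#' @export
default_name_suffixes <- function() {
  c("incorporated", "inc", "limited", "ltd", "llc",
    "corporation", "corp", "co")
}

#' Canonicalize a partner name
#'
#' Deterministic normalization used everywhere a partner name is matched
#' across tables: trims outer whitespace, collapses internal whitespace runs,
#' case-folds, strips trailing corporate suffixes (with optional preceding
#' comma) and trailing punctuation. Idempotent. Empty or missing input maps
#' to the sentinel `"NA"`, the class used for funding whose recipient is not
#' yet awarded.
#'
#' @param x Character vector of raw names.
#' @param suffixes Lower-case suffix tokens to strip (see
#'   [default_name_suffixes()]).
#' @return Character vector of canonical names.
#' @export
#' @examples
#' normalize_name("  Acme  Health Inc.") # "acme health"
#' normalize_name("")                    # "NA"
normalize_name <- function(x, suffixes = default_name_suffixes()) {
  out <- as.character(x)
  out[is.na(out)] <- ""
  out <- tolower(trimws(gsub("[[:space:]]+", " ", out)))
  if (length(suffixes)) {
    pat <- paste0("[,[:space:]]+(", paste(suffixes, collapse = "|"),
                  ")[[:punct:]]*$")
    repeat {
      stripped <- trimws(sub(pat, "", out))
      stripped <- sub("[,\\.]+$", "", stripped)
      if (identical(stripped, out)) break
      out <- stripped
    }
  } else {
    out <- sub("[,\\.]+$", "", out)
  }
  out[out %in% c("", "na", "n/a", "not available")] <- "NA"
  out
}

stop_rows <- function(msg, rows, class) {
  shown <- head(rows, 5L)
  abort(
    paste0(msg, " (row", if (length(rows) > 1) "s", " ",
           paste(shown, collapse = ", "),
           if (length(rows) > length(shown)) ", ..." else "", ")"),
    class = class
  )
}

parse_amount_cents <- function(x, rows_label = "amount") {
  amt <- suppressWarnings(as.numeric(gsub("[$, ]", "", as.character(x))))
  bad <- which(is.na(amt) & !is.na(x) | is.na(x))
  if (length(bad)) {
    stop_rows(paste0("non-numeric or missing ", rows_label), bad,
              "copcost_error_bad_amount")
  }
  neg <- which(amt < 0)
  if (length(neg)) {
    stop_rows(paste0("negative ", rows_label), neg,
              "copcost_error_negative_amount")
  }
  as_cents(amt)
}

parse_year <- function(x, field = "year") {
  yr <- suppressWarnings(as.integer(as.character(x)))
  bad <- which(is.na(yr))
  if (length(bad)) {
    stop_rows(paste0("non-integer ", field), bad, "copcost_error_bad_year")
  }
  yr
}

parse_rate <- function(x, field) {
  r <- suppressWarnings(as.numeric(as.character(x)))
  bad <- which(is.na(r) | r < 0 | r > 1)
  if (length(bad)) {
    stop_rows(paste0(field, " outside [0, 1]"), bad,
              "copcost_error_bad_rate")
  }
  r
}

#' Read and validate one input table
#'
#' Reads a CSV in the documented schema for `kind`, validates every field,
#' canonicalizes partner names and converts dollar amounts to integer cents
#' (column `amount_cents`). Validation failures raise classed errors naming
#' the offending rows: `copcost_error_missing_file`,
#' `copcost_error_missing_column`, `copcost_error_bad_amount`,
#' `copcost_error_negative_amount`, `copcost_error_bad_year`,
#' `copcost_error_bad_rate`, `copcost_error_bad_category`,
#' `copcost_error_bad_class`, `copcost_error_overlapping_periods`.
#'
#' @param path Path to a CSV file.
#' @param kind Table kind; see [cop_schema()].
#' @param suffixes Suffix tokens for [normalize_name()].
#' @return A validated tibble. Funding, sub-award and cross-cutting tables
#'   carry `amount_cents`; partner-name columns are canonical.
#' @export
read_cop_table <- function(path, kind, suffixes = default_name_suffixes()) {
  kind <- match.arg(kind, cop_table_kinds)
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path),
          class = "copcost_error_missing_file")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_cop_table(raw, kind, suffixes)
}

#' Validate an in-memory table against a schema
#'
#' Same contract as [read_cop_table()] but starting from a data frame, used
#' by the synthetic generator round-trip and by callers who assemble tables
#' programmatically.
#'
#' @param x A data frame with the columns of [cop_schema()] for `kind`.
#' @inheritParams read_cop_table
#' @return A validated tibble.
#' @export
validate_cop_table <- function(x, kind, suffixes = default_name_suffixes()) {
  kind <- match.arg(kind, cop_table_kinds)
  need <- cop_schema(kind)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s) for ", kind, " table: ",
                 paste(missing_cols, collapse = ", ")),
          class = "copcost_error_missing_column")
  }
  x <- tibble::as_tibble(x)[need]
  out <- switch(kind,
    funding = x |>
      mutate(
        country = as.character(.data$country),
        year = parse_year(.data$year),
        mechanism_id = as.character(.data$mechanism_id),
        partner = normalize_name(.data$partner, suffixes),
        org_type = as.character(.data$org_type),
        agency = trimws(as.character(.data$agency)),
        budget_code = toupper(trimws(as.character(.data$budget_code))),
        amount_cents = parse_amount_cents(.data$amount),
        amount = NULL
      ),
    subawards = x |>
      mutate(
        prime_partner = normalize_name(.data$prime_partner, suffixes),
        agency = trimws(as.character(.data$agency)),
        year = parse_year(.data$year),
        sub_partner = normalize_name(.data$sub_partner, suffixes),
        amount_cents = parse_amount_cents(.data$amount),
        amount = NULL
      ),
    crosscutting = x |>
      mutate(
        mechanism_id = as.character(.data$mechanism_id),
        partner = normalize_name(.data$partner, suffixes),
        agency = trimws(as.character(.data$agency)),
        year = parse_year(.data$year),
        category = toupper(trimws(as.character(.data$category))),
        amount_cents = parse_amount_cents(.data$amount),
        amount = NULL
      ),
    classes = x |>
      mutate(
        partner = normalize_name(.data$partner, suffixes),
        class = toupper(trimws(as.character(.data$class)))
      ),
    rates = x |>
      mutate(
        partner = normalize_name(.data$partner, suffixes),
        period_start = parse_year(.data$period_start, "period_start"),
        period_end = parse_year(.data$period_end, "period_end"),
        on_campus_osa = parse_rate(.data$on_campus_osa, "on_campus_osa"),
        off_campus_osa = parse_rate(.data$off_campus_osa, "off_campus_osa")
      )
  )
  if (kind == "funding") {
    blank <- which(out$budget_code == "")
    if (length(blank)) {
      stop_rows("empty budget_code", blank, "copcost_error_missing_column")
    }
  }
  if (kind == "subawards") {
    self <- which(out$prime_partner == out$sub_partner &
                    out$prime_partner != "NA")
    if (length(self)) {
      stop_rows("sub-award where prime and sub-partner coincide", self,
                "copcost_error_self_subaward")
    }
  }
  if (kind == "crosscutting") {
    bad <- which(!out$category %in% crosscutting_categories)
    if (length(bad)) {
      stop_rows(paste0("unknown cross-cutting category (expected one of ",
                       paste(crosscutting_categories, collapse = ", "), ")"),
                bad, "copcost_error_bad_category")
    }
  }
  if (kind == "classes") {
    bad <- which(!out$class %in% partner_classes)
    if (length(bad)) {
      stop_rows(paste0("unknown partner class (expected one of ",
                       paste(partner_classes, collapse = ", "), ")"),
                bad, "copcost_error_bad_class")
    }
    dup <- out |> count(.data$partner) |> filter(.data$n > 1)
    if (nrow(dup)) {
      abort(paste0("partner(s) classified more than once: ",
                   paste(head(dup$partner, 5L), collapse = ", ")),
            class = "copcost_error_duplicate_class")
    }
  }
  if (kind == "rates") {
    bad <- which(out$period_end < out$period_start)
    if (length(bad)) {
      stop_rows("rate period ends before it starts", bad,
                "copcost_error_bad_year")
    }
    inv <- which(out$off_campus_osa > out$on_campus_osa)
    if (length(inv)) {
      warn(paste0("off-campus OSA rate exceeds on-campus for: ",
                  paste(unique(out$partner[inv]), collapse = ", ")))
    }
    overlaps <- out |>
      arrange(.data$partner, .data$period_start) |>
      group_by(.data$partner) |>
      filter(n() > 1,
             coalesce(.data$period_start <= lag(.data$period_end),
                      FALSE)) |>
      ungroup()
    if (nrow(overlaps)) {
      abort(paste0("overlapping rate periods for partner(s): ",
                   paste(unique(overlaps$partner), collapse = ", ")),
            class = "copcost_error_overlapping_periods")
    }
  }
  out
}
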
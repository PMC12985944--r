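#' Write and read an NPX cohort as a long-format CSV
#'
#' The on-disk format is a single long CSV with one row per measurement and
#' columns `sample_id, participant_id, protein, panel, npx, lod, date, age,
#' sex, group` (dates ISO-8601, missing NPX as empty cells). `read_npx_csv()`
#' inverts `write_npx_csv()` exactly, including missing values and dates; the
#' `below_lod` flag is reconstructed from `npx < lod`.
#'
#' @param npx Long-format NPX tibble as produced by [generate_cohort()].
#' @param meta Matching per-sample metadata tibble.
#' @param path File path of the CSV.
#' @return `write_npx_csv()` returns `path` invisibly; `read_npx_csv()`
#'   returns `list(npx = , meta = )`.
#' @export
write_npx_csv <- function(npx, meta, path) {
  joined <- npx %>%
    left_join(meta %>% select("sample_id", "participant_id", "age", "sex",
                              "group"),
              by = "sample_id") %>%
    select("sample_id", "participant_id", "protein", "panel", "npx", "lod",
           "date", "age", "sex", "group")
  readr::write_csv(joined, path, na = "")
  invisible(path)
}

#' @rdname write_npx_csv
#' @export
read_npx_csv <- function(path) {
  required <- c("sample_id", "participant_id", "protein", "panel", "npx",
                "lod", "date", "age", "sex", "group")
  header <- readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                            show_col_types = FALSE)
  missing_cols <- setdiff(required, names(header))
  if (length(missing_cols) > 0L)
    stop("NPX file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      participant_id = readr::col_character(),
      protein = readr::col_character(),
      panel = readr::col_character(),
      npx = readr::col_double(),
      lod = readr::col_double(),
      date = readr::col_character(),
      age = readr::col_double(),
      sex = readr::col_integer(),
      group = readr::col_character()
    ),
    na = "", progress = FALSE
  )

  dup <- duplicated(raw[c("sample_id", "protein")])
  if (any(dup))
    stop("duplicate (sample_id, protein) keys at row(s): ",
         paste(head(which(dup), 10L), collapse = ", "), call. = FALSE)

  parsed_date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad_date <- !is.na(raw$date) & is.na(parsed_date)
  if (any(bad_date))
    stop("unparseable date(s) at row(s): ",
         paste(head(which(bad_date), 10L), collapse = ", "), call. = FALSE)
  if (any(is.na(raw$date)))
    stop("missing date(s) at row(s): ",
         paste(head(which(is.na(raw$date)), 10L), collapse = ", "),
         call. = FALSE)

  npx <- tibble(
    sample_id = raw$sample_id,
    protein = raw$protein,
    panel = raw$panel,
    npx = raw$npx,
    lod = raw$lod,
    below_lod = !is.na(raw$npx) & raw$npx < raw$lod,
    date = parsed_date
  )
  meta <- raw %>%
    mutate(date = parsed_date,
           group = factor(.data$group, levels = c("normal", "case"))) %>%
    distinct(.data$sample_id, .keep_all = TRUE) %>%
    select("sample_id", "participant_id", "age", "sex", "group", "date") %>%
    mutate(age = as.integer(.data$age), sex = as.integer(.data$sex))
  list(npx = npx, meta = meta)
}

#' Reshape a long NPX table to a wide sample-by-protein matrix
#'
#' @param npx Long-format NPX tibble.
#' @return A tibble with one row per sample (`sample_id` first column) and one
#'   column per protein holding NPX values.
#' @export
npx_wide <- function(npx) {
  npx %>%
    select("sample_id", "protein", "npx") %>%
    tidyr::pivot_wider(names_from = "protein", values_from = "npx")
}
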
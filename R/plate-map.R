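well_roles <- c("vehicle_control", "positive_control", "treatment", "empty")

#' Parse a well address like "B07"
#'
#' Rows are letters A-P, columns 1-24 (384-well convention). Addresses are
#' rendered back zero-padded ("A01").
#'
#' @param well Character vector of addresses.
#' @return Tibble with columns `well`, `row` (integer, A = 1), `col`.
#' @export
parse_well <- function(well) {
  m <- regmatches(well, regexec("^([A-Pa-p])0*([0-9]{1,2})$", well))
  bad <- lengths(m) != 3
  if (any(bad)) stop("malformed well address: ", paste(well[bad], collapse = ", "))
  row <- match(toupper(vapply(m, `[`, "", 2)), LETTERS)
  col <- as.integer(vapply(m, `[`, "", 3))
  if (any(col < 1 | col > 24)) stop("well column out of range 1-24")
  tibble(well = format_well(row, col), row = row, col = col)
}

#' @rdname parse_well
#' @param row,col Integer row (A = 1) and column.
#' @export
format_well <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

#' Read a plate map
#'
#' Expects a CSV with header `well,role,drug,concentration_nM,replicate,sample`.
#' Roles are `vehicle_control`, `positive_control`, `treatment` or `empty`.
#' Treatment and positive-control wells must carry a drug and a positive
#' concentration; vehicle wells must carry neither. Within each drug the
#' tested concentrations must form a geometric dilution series with the
#' stated factor (default 1:5, five concentrations, duplicate wells).
#'
#' @param path CSV file path.
#' @param dilution_factor Expected ratio between consecutive concentrations.
#' @param n_concentrations,n_replicates Reference layout shape (recorded as
#'   attributes; not enforced per drug so partial plates load).
#' @return A `plate_layout`: a tibble with columns `well`, `row`, `col`,
#'   `role`, `drug`, `concentration_nM`, `replicate`, `sample`.
#' @export
read_plate_map <- function(path, dilution_factor = 5,
                           n_concentrations = 5, n_replicates = 2) {
  df <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    role = readr::col_character(),
    drug = readr::col_character(),
    concentration_nM = readr::col_double(),
    replicate = readr::col_integer(),
    sample = readr::col_character()
  ))
  plate_layout(df, dilution_factor = dilution_factor,
               n_concentrations = n_concentrations,
               n_replicates = n_replicates)
}

#' Construct and validate a plate layout from a data frame
#'
#' @param df Data frame with the [read_plate_map()] columns.
#' @inheritParams read_plate_map
#' @export
plate_layout <- function(df, dilution_factor = 5,
                         n_concentrations = 5, n_replicates = 2) {
  need <- c("well", "role", "drug", "concentration_nM", "replicate", "sample")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate map missing column(s): ", paste(miss, collapse = ", "))
  addr <- parse_well(df$well)
  out <- tibble(
    well = addr$well, row = addr$row, col = addr$col,
    role = df$role, drug = df$drug,
    concentration_nM = as.numeric(df$concentration_nM),
    replicate = as.integer(df$replicate), sample = df$sample
  )
  if (anyDuplicated(out$well)) {
    stop("duplicate well address: ",
         paste(unique(out$well[duplicated(out$well)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(out$role), well_roles)
  if (length(bad_role)) stop("unknown role token: ", paste(bad_role, collapse = ", "))

  dosed <- out$role %in% c("treatment", "positive_control")
  if (any(dosed & (is.na(out$drug) | is.na(out$concentration_nM)))) {
    stop("treatment/positive_control wells must have drug and concentration set")
  }
  if (any(out$concentration_nM[dosed] <= 0)) {
    stop("concentrations must be > 0")
  }
  veh <- out$role == "vehicle_control"
  if (any(veh & (!is.na(out$drug) | !is.na(out$concentration_nM)))) {
    stop("vehicle_control wells must not carry a drug or concentration")
  }

  # control-mean normalization needs >= 2 vehicle wells per treated sample
  treated_samples <- unique(out$sample[out$role == "treatment"])
  for (s in treated_samples) {
    n_ctrl <- sum(veh & out$sample == s)
    if (n_ctrl < 2) {
      stop("sample ", s, " has ", n_ctrl,
           " vehicle_control wells; at least 2 are required")
    }
  }

  check_dilution_series(out, dilution_factor)
  structure(out,
            class = c("plate_layout", class(tibble())),
            dilution_factor = dilution_factor,
            n_concentrations = n_concentrations,
            n_replicates = n_replicates)
}

check_dilution_series <- function(layout, factor, rtol = 1e-6) {
  tr <- layout[layout$role == "treatment", , drop = FALSE]
  for (d in unique(tr$drug)) {
    conc <- sort(unique(tr$concentration_nM[tr$drug == d]))
    if (length(conc) < 2) next
    ratios <- conc[-1] / conc[-length(conc)]
    if (any(abs(ratios - factor) > rtol * factor)) {
      stop("concentrations for drug ", d,
           " do not form a 1:", factor, " geometric series")
    }
  }
  invisible(TRUE)
}

#' Write a plate map CSV
#'
#' Inverse of [read_plate_map()]; `read_plate_map(write_plate_map(x, f))`
#' preserves every field.
#'
#' @param layout A `plate_layout`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(layout, path) {
  df <- as_tibble(layout)[, c("well", "role", "drug", "concentration_nM",
                              "replicate", "sample")]
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d wells (%d treatment, %d vehicle, %d positive, %d empty)\n",
              nrow(x), sum(x$role == "treatment"), sum(x$role == "vehicle_control"),
              sum(x$role == "positive_control"), sum(x$role == "empty")))
  NextMethod()
}
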
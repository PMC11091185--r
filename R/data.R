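#' Long-format ordinal response dataset with country covariate
#'
#' Validates and indexes a long-format table of ordinal responses
#' (person, country, item, category on a `1..K` scale) together with a
#' country-level covariate table (e.g., the Human Development Index).
#' The raw covariate is standardized at construction time to mean 0 and
#' sample SD 1 (denominator `G - 1`); the transform is stored so values
#' can be mapped back to the raw scale.
#'
#' Validation errors are specific and name the offending rows: responses
#' outside `1..K`, duplicated (person, item) cells, persons appearing in
#' more than one country, and countries without a covariate row each
#' raise a distinct error.
#'
#' @param responses data frame with columns `person_id`, `country_id`,
#'   `item_id`, `response` (integer `1..K` or `NA`).
#' @param covariates data frame with columns `country_id` and a numeric
#'   covariate column (the second column is used, whatever its name).
#' @param K integer category count of the rating scale.
#' @return an object of class `response_dataset` with components
#'   `responses`, `persons`, `items`, `countries` (including raw and
#'   standardized covariate), `K`, row-wise `person_index`/`item_index`,
#'   and the stored `covariate_transform`.
#' @export
response_dataset <- function(responses, covariates, K) {
  if (length(K) != 1L || !is.finite(K) || K != as.integer(K) || K < 2) {
    stop("`K` must be a single integer >= 2.", call. = FALSE)
  }
  K <- as.integer(K)
  responses <- as.data.frame(responses)
  covariates <- as.data.frame(covariates)
  need <- c("person_id", "country_id", "item_id", "response")
  if (!all(need %in% names(responses))) {
    stop("`responses` must have columns person_id, country_id, item_id, ",
      "response.",
      call. = FALSE
    )
  }
  if (!"country_id" %in% names(covariates) || ncol(covariates) < 2L) {
    stop("`covariates` must have a country_id column and a covariate ",
      "column.",
      call. = FALSE
    )
  }
  resp <- responses$response
  if (is.logical(resp) && all(is.na(resp))) resp <- as.integer(resp)
  if (!is.numeric(resp)) {
    stop("`response` must be numeric.", call. = FALSE)
  }
  out_of_range <- which(!is.na(resp) &
    (resp < 1 | resp > K | resp != floor(resp)))
  if (length(out_of_range)) {
    stop(sprintf(
      "out-of-range response at row %d: value %s on a %d-point scale",
      out_of_range[1L], resp[out_of_range[1L]], K
    ), call. = FALSE)
  }
  cell <- paste(responses$person_id, responses$item_id, sep = "\r")
  if (anyDuplicated(cell)) {
    d <- which(duplicated(cell))[1L]
    stop(sprintf(
      "duplicate cell at row %d: person '%s', item '%s' appears more ",
      d, responses$person_id[d], responses$item_id[d]
    ), call. = FALSE)
  }
  pc <- unique(responses[, c("person_id", "country_id")])
  if (anyDuplicated(pc$person_id)) {
    p <- pc$person_id[duplicated(pc$person_id)][1L]
    stop(sprintf("person '%s' is assigned to more than one country", p),
      call. = FALSE
    )
  }
  countries_seen <- unique(as.character(responses$country_id))
  cov_countries <- as.character(covariates$country_id)
  missing_cov <- setdiff(countries_seen, cov_countries)
  if (length(missing_cov)) {
    stop(sprintf(
      "country '%s' has no covariate row", missing_cov[1L]
    ), call. = FALSE)
  }
  covariates <- covariates[cov_countries %in% countries_seen, , drop = FALSE]
  x_raw <- covariates[[2L]]
  if (!is.numeric(x_raw) || anyNA(x_raw)) {
    stop("covariate values must be numeric and complete.", call. = FALSE)
  }
  ctr <- mean(x_raw)
  scl <- stats::sd(x_raw)
  if (!is.finite(scl) || scl == 0) {
    stop("covariate has zero variance; cannot standardize.", call. = FALSE)
  }
  countries <- data.frame(
    country_id = as.character(covariates$country_id),
    x_raw = x_raw,
    x = (x_raw - ctr) / scl,
    stringsAsFactors = FALSE
  )
  countries <- countries[order(countries$country_id), , drop = FALSE]
  rownames(countries) <- NULL

  persons <- data.frame(
    person_id = as.character(pc$person_id),
    country_id = as.character(pc$country_id),
    stringsAsFactors = FALSE
  )
  persons <- persons[order(persons$person_id), , drop = FALSE]
  persons$country_index <- match(persons$country_id, countries$country_id)
  rownames(persons) <- NULL

  items <- data.frame(
    item_id = sort(unique(as.character(responses$item_id))),
    stringsAsFactors = FALSE
  )

  responses$response <- as.integer(resp)
  structure(
    list(
      responses = responses,
      persons = persons,
      items = items,
      countries = countries,
      K = K,
      person_index = match(as.character(responses$person_id),
        persons$person_id),
      item_index = match(as.character(responses$item_id), items$item_id),
      covariate_transform = list(center = ctr, scale = scl)
    ),
    class = "response_dataset"
  )
}

#' @export
print.response_dataset <- function(x, ...) {
  cat(
    "<response_dataset>", nrow(x$persons), "persons,",
    nrow(x$countries), "countries,", nrow(x$items), "items, K =", x$K, "\n"
  )
  n_miss <- sum(is.na(x$responses$response))
  cat(
    " ", nrow(x$responses), "response cells,", n_miss, "missing\n"
  )
  invisible(x)
}

#' Read and validate response and covariate CSV files
#'
#' Reads a long-format response CSV (`person_id`, `country_id`,
#' `item_id`, `response`) and a country covariate CSV (`country_id`,
#' covariate), then validates and standardizes via
#' [response_dataset()]. A short summary of persons, countries, items
#' and missingness is printed unless `quiet = TRUE`.
#'
#' @param responses_path path to the response CSV.
#' @param covariates_path path to the covariate CSV.
#' @param K integer category count.
#' @param quiet suppress the summary line.
#' @return a validated [response_dataset()].
#' @export
read_and_validate <- function(responses_path, covariates_path, K,
                              quiet = FALSE) {
  responses <- utils::read.csv(responses_path, stringsAsFactors = FALSE)
  covariates <- utils::read.csv(covariates_path, stringsAsFactors = FALSE)
  ds <- response_dataset(responses, covariates, K)
  if (!quiet) print(ds)
  ds
}

#' Write a response dataset to CSV files
#'
#' Inverse of [read_and_validate()]: writes the long-format response
#' table and the country covariate table (raw scale) as CSV.
#'
#' @param data a [response_dataset()].
#' @param responses_path,covariates_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_dataset <- function(data, responses_path, covariates_path) {
  stopifnot(inherits(data, "response_dataset"))
  utils::write.csv(data$responses, responses_path, row.names = FALSE)
  cov <- data.frame(
    country_id = data$countries$country_id,
    x = data$countries$x_raw
  )
  utils::write.csv(cov, covariates_path, row.names = FALSE)
  invisible(c(responses_path, covariates_path))
}

#' Convert a wide persons-by-items response matrix to long format
#'
#' @param wide data frame with columns `person_id`, `country_id`, and one
#'   column per item.
#' @return long-format data frame with columns `person_id`,
#'   `country_id`, `item_id`, `response`.
#' @export
wide_to_long <- function(wide) {
  wide <- as.data.frame(wide)
  id_cols <- c("person_id", "country_id")
  if (!all(id_cols %in% names(wide))) {
    stop("`wide` must have person_id and country_id columns.", call. = FALSE)
  }
  item_cols <- setdiff(names(wide), id_cols)
  if (!length(item_cols)) stop("no item columns found.", call. = FALSE)
  long <- do.call(rbind, lapply(item_cols, function(it) {
    data.frame(
      person_id = wide$person_id,
      country_id = wide$country_id,
      item_id = it,
      response = wide[[it]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(long) <- NULL
  long
}
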
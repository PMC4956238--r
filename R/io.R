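#' Read a baseline questionnaire CSV
#'
#' One row per participant; required columns are `id`, the OMPSQ items
#' `omp_5` .. `omp_25`, the checkbox columns `omp_8_nw`, `omp_16_nw`,
#' `omp_17_nw` and the HKF-R 10 items `hkf_1` .. `hkf_27`. The dialect is
#' fixed: comma separator, dot decimal, UTF-8, header required. Blank cells
#' and the configured NA tokens parse to missing; decimal commas are
#' rejected with a clear message rather than silently coerced.
#'
#' @param path CSV file path.
#' @param na_tokens Strings treated as missing (besides the empty cell).
#' @return Tibble with typed columns (numeric items, logical checkboxes).
#' @export
read_baseline <- function(path, na_tokens = c("", "NA")) {
  item_cols <- c(paste0("omp_", 5:25), paste0("hkf_", 1:27))
  cb_cols <- paste0("omp_", c(8, 16, 17), "_nw")
  read_typed_csv(path, required = c("id", item_cols, cb_cols),
                 numeric_cols = item_cols, logical_cols = cb_cols,
                 na_tokens = na_tokens)
}

#' Read a 6-month follow-up CSV
#'
#' Required columns: `id`, `fu_omp_10`, `fu_omp_11`, `fu_omp_21` ..
#' `fu_omp_25`, `fu_sickdays`, `fu_hkf_5`. A row missing an outcome's key
#' variable is retained; only that outcome's label is absent.
#'
#' @inheritParams read_baseline
#' @return Tibble with typed columns.
#' @export
read_followup <- function(path, na_tokens = c("", "NA")) {
  num_cols <- c("fu_omp_10", "fu_omp_11", paste0("fu_omp_", 21:25),
                "fu_sickdays", "fu_hkf_5")
  read_typed_csv(path, required = c("id", num_cols),
                 numeric_cols = num_cols, logical_cols = character(0),
                 na_tokens = na_tokens)
}

read_typed_csv <- function(path, required, numeric_cols, logical_cols,
                           na_tokens) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop(path, " lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$id)) {
    stop(path, ": duplicate participant id '",
         raw$id[anyDuplicated(raw$id)], "'", call. = FALSE)
  }
  for (cl in numeric_cols) {
    x <- trimws(raw[[cl]])
    x[x %in% na_tokens] <- NA
    if (any(grepl(",", x))) {
      i <- which(grepl(",", x))[1]
      stop(sprintf("%s: decimal comma in column %s, row %d ('%s'); %s",
                   path, cl, i, x[i],
                   "use a dot decimal separator"), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(v)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("%s: malformed number in column %s, row %d ('%s')",
                   path, cl, i, x[i]), call. = FALSE)
    }
    raw[[cl]] <- v
  }
  for (cl in logical_cols) {
    raw[[cl]] <- isTRUE_vec(raw[[cl]])
  }
  tibble::as_tibble(raw)
}

#' Read / write an OMPSQ item table as YAML
#'
#' The scored-item table (see [ompsq_item_spec()]) is configuration, not
#' code: an alternate item numbering or the original Swedish 4-210 scaling
#' is a data change. The YAML is a sequence of mappings with keys
#' `item_id`, `scale_min`, `scale_max`, `inverted`, `doubled`,
#' `checkbox_allowed`.
#'
#' @param path YAML file path.
#' @return `read_item_spec`: the item tibble.
#' @export
read_item_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  items <- tibble::as_tibble(do.call(rbind, lapply(raw, as.data.frame)))
  items$item_id <- as.integer(items$item_id)
  items$scale_min <- as.integer(items$scale_min)
  items$scale_max <- as.integer(items$scale_max)
  check_item_spec(items)
  items
}

#' @rdname read_item_spec
#' @param items Item tibble to serialize.
#' @export
write_item_spec <- function(items, path) {
  check_item_spec(items)
  yaml::write_yaml(lapply(seq_len(nrow(items)), function(i) {
    as.list(items[i, ])
  }), path)
  invisible(path)
}

#' Read / write an HKF-R 10 weight specification as YAML
#'
#' Format: a mapping with `intercept` and a `terms` sequence of
#' `{target: <item_id>, weight: <real>}` entries covering every scored item
#' exactly once.
#'
#' @param path YAML file path.
#' @return `read_weight_spec`: list with `intercept` and named `weights`.
#' @export
read_weight_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!all(c("intercept", "terms") %in% names(raw))) {
    stop("weight spec YAML needs 'intercept' and 'terms'", call. = FALSE)
  }
  w <- stats::setNames(vapply(raw$terms, function(t) as.numeric(t$weight), 0),
                       vapply(raw$terms, function(t) as.character(t$target), ""))
  if (anyDuplicated(names(w))) {
    stop("weight spec assigns an item more than once", call. = FALSE)
  }
  list(intercept = as.numeric(raw$intercept), weights = w)
}

#' @rdname read_weight_spec
#' @param weights Weight spec to serialize.
#' @export
write_weight_spec <- function(weights, path) {
  yaml::write_yaml(list(
    intercept = weights$intercept,
    terms = lapply(names(weights$weights), function(nm) {
      list(target = nm, weight = unname(weights$weights[[nm]]))
    })
  ), path)
  invisible(path)
}
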
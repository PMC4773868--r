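MODEL_FORMAT_VERSION <- 1L

#' Construct a labelled dataset
#'
#' Pairs of validated sequence records and soluble yields (mg/l), the input
#' to training and evaluation.
#'
#' @param records List of [sequence_record()] objects with unique ids.
#' @param yield Positive numeric vector of soluble yields in mg/l, one per
#'   record.
#' @param meta Optional named list of provenance metadata.
#' @return Object of class `LabelledDataset` with fields `records`, `yield`,
#'   `meta`.
#' @export
labelled_dataset <- function(records, yield, meta = list()) {
  if (length(records) != length(yield)) {
    stop("invalid input: records and yields differ in length", call. = FALSE)
  }
  ok <- vapply(records, inherits, logical(1), "SequenceRecord")
  if (!all(ok)) {
    stop(sprintf("invalid input: element %d is not a SequenceRecord",
                 which(!ok)[1L]), call. = FALSE)
  }
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids) > 0L) {
    stop(sprintf("invalid input: duplicate id '%s'",
                 ids[duplicated(ids)][1L]), call. = FALSE)
  }
  if (!is.numeric(yield) || any(!is.finite(yield)) || any(yield <= 0)) {
    stop("invalid input: yields must be positive finite mg/l values",
         call. = FALSE)
  }
  structure(list(records = records, yield = as.numeric(yield), meta = meta),
            class = "LabelledDataset")
}

#' @export
print.LabelledDataset <- function(x, ...) {
  cls <- table(yield_to_class(x$yield))
  cat(sprintf("LabelledDataset: %d instances (%s)\n", length(x$yield),
              paste(names(cls), as.vector(cls), sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.LabelledDataset <- function(x, ...) {
  data.frame(id = vapply(x$records, function(r) r$id, character(1)),
             sequence = vapply(x$records, function(r) r$sequence, character(1)),
             yield_mg_per_l = x$yield,
             stringsAsFactors = FALSE)
}

#' Read a labelled dataset table
#'
#' Tab-separated file with header columns `id`, `sequence`,
#' `yield_mg_per_l`. Every row is validated (legal residues, positive
#' numeric yield, unique ids); errors name the offending row.
#'
#' @param path Path to the TSV file.
#' @return A [labelled_dataset()].
#' @export
read_dataset_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "sequence", "yield_mg_per_l")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("invalid table '%s': missing column '%s'", path, miss[1L]),
         call. = FALSE)
  }
  yields <- suppressWarnings(as.numeric(tab$yield_mg_per_l))
  bad <- which(!is.finite(yields) | yields <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("invalid table '%s': row %d has non-positive or non-numeric yield '%s'",
                 path, bad[1L], tab$yield_mg_per_l[bad[1L]]), call. = FALSE)
  }
  dup <- which(duplicated(tab$id))
  if (length(dup) > 0L) {
    stop(sprintf("invalid table '%s': row %d duplicates id '%s'",
                 path, dup[1L], tab$id[dup[1L]]), call. = FALSE)
  }
  records <- lapply(seq_len(nrow(tab)), function(i) {
    tryCatch(sequence_record(tab$id[i], tab$sequence[i]), error = function(e) {
      stop(sprintf("invalid table '%s': row %d: %s", path, i,
                   conditionMessage(e)), call. = FALSE)
    })
  })
  labelled_dataset(records, yields, meta = list(source = path))
}

#' Write a labelled dataset table
#'
#' @param dataset A [labelled_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_table <- function(dataset, path) {
  utils::write.table(as.data.frame(dataset), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature table
#'
#' One row per sequence, first column `id`, then one named column per
#' feature, tab-separated.
#'
#' @param x Feature matrix from [feature_matrix()] (rownames = ids).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits by class (from [yield_to_class()]) with largest-remainder
#' apportionment of `round(n * test_fraction)` test slots, guaranteeing
#' every class at least one instance in each partition. Deterministic given
#' the seed.
#'
#' @param dataset A [labelled_dataset()] with >= 2 instances per class.
#' @param test_fraction Fraction of instances held out (default 0.15).
#' @param seed Integer seed.
#' @return List with `train` and `test`, both `LabelledDataset`s.
#' @export
split_dataset <- function(dataset, test_fraction = 0.15, seed = 1L) {
  stopifnot(inherits(dataset, "LabelledDataset"))
  n <- length(dataset$yield)
  classes <- yield_to_class(dataset$yield)
  counts <- table(classes)
  if (any(counts < 2L)) {
    stop(sprintf("stratification error: class '%s' has fewer than 2 instances",
                 names(counts)[counts < 2L][1L]), call. = FALSE)
  }
  n_test <- round(n * test_fraction)
  k <- length(counts)
  if (test_fraction <= 0 || n_test < k || n - n_test < k) {
    stop("invalid argument: test fraction leaves a partition without all classes",
         call. = FALSE)
  }
  quota <- as.vector(counts) * test_fraction
  take <- floor(quota)
  rem <- n_test - sum(take)
  if (rem > 0) {
    ord <- order(quota - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  take <- pmin(pmax(take, 1L), as.vector(counts) - 1L)
  # re-balance if the floor/ceiling adjustments changed the total
  while (sum(take) > n_test) {
    j <- which(take > 1L)[which.max(take[which(take > 1L)])]
    take[j] <- take[j] - 1L
  }
  while (sum(take) < n_test) {
    room <- which(take < as.vector(counts) - 1L)
    j <- room[which.max(as.vector(counts)[room] - take[room])]
    take[j] <- take[j] + 1L
  }
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(seq_along(counts), function(ci) {
      idx <- which(classes == names(counts)[ci])
      sample(idx, take[ci])
    }))
  })
  test_idx <- sort(test_idx)
  subset_ds <- function(idx) {
    labelled_dataset(dataset$records[idx], dataset$yield[idx], dataset$meta)
  }
  list(train = subset_ds(setdiff(seq_len(n), test_idx)),
       test = subset_ds(test_idx))
}

#' Save a trained model bundle
#'
#' The bundle is a single JSON text file carrying a format version, the
#' training seed and the full model (feature subsets, standardizers,
#' support vectors and dual coefficients, Platt and grid parameters,
#' registry groups) serialized losslessly.
#'
#' @param model A [train_two_stage()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "TwoStageModel"))
  bundle <- list(
    format_version = MODEL_FORMAT_VERSION,
    package = "periyield",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = model$config$seed,
    # base64-wrapped binary serialization: bit-exact doubles, text bundle
    payload = jsonlite::base64_enc(serialize(model, NULL))
  )
  writeLines(jsonlite::toJSON(bundle, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a saved model bundle
#'
#' @param path Path written by [save_model()].
#' @return The `TwoStageModel`; predictions are identical to the saved
#'   model's.
#' @export
load_model <- function(path) {
  bundle <- tryCatch(jsonlite::fromJSON(path),
                     error = function(e) {
                       stop(sprintf("load error: corrupted model bundle '%s' (%s)",
                                    path, conditionMessage(e)), call. = FALSE)
                     })
  if (is.null(bundle$format_version) || is.null(bundle$payload)) {
    stop(sprintf("load error: '%s' is not a model bundle", path),
         call. = FALSE)
  }
  if (bundle$format_version > MODEL_FORMAT_VERSION) {
    stop(sprintf("load error: bundle format version %d is newer than supported version %d",
                 bundle$format_version, MODEL_FORMAT_VERSION), call. = FALSE)
  }
  model <- tryCatch(unserialize(jsonlite::base64_dec(bundle$payload)),
                    error = function(e) {
                      stop(sprintf("load error: corrupted payload in '%s'", path),
                           call. = FALSE)
                    })
  if (!inherits(model, "TwoStageModel")) {
    stop(sprintf("load error: '%s' does not contain a TwoStageModel", path),
         call. = FALSE)
  }
  model
}
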
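#' Enumerate the acquisition files of a redundancy cohort
#'
#' The cohort design multiplies each patient into many classifier instances:
#' `containers_per_patient` urine containers, `acquisitions_per_container`
#' repeated acquisitions of each container, and 32 sensor curves per
#' acquisition. At the standard design (20 + 20 patients, 4 containers,
#' 5 acquisitions) this yields 800 files of 32 curves, i.e. 640 instances
#' per patient.
#'
#' @param n_patients_per_class patients in each class (benign hyperplasia,
#'   label 0; prostate cancer, label 1); a length-2 vector `c(hbp, cap)` or a
#'   single count used for both.
#' @param containers_per_patient containers collected per patient (default 4).
#' @param acquisitions_per_container repeated acquisitions per container
#'   (default 5).
#' @return a manifest `data.frame` with one row per acquisition file:
#'   `file`, `patient_id`, `label`, `container`, `acquisition`; each file
#'   references 32 curves.
#' @export
enumerate_cohort <- function(n_patients_per_class,
                             containers_per_patient = 4L,
                             acquisitions_per_container = 5L) {
  n <- rep(as.integer(n_patients_per_class), length.out = 2L)
  stopifnot(all(n >= 0L), sum(n) >= 1L, containers_per_patient >= 1L,
            acquisitions_per_container >= 1L)
  patients <- data.frame(
    patient_id = c(sprintf("HBP%02d", seq_len(n[1L])),
                   sprintf("CaP%02d", seq_len(n[2L]))),
    label = rep(c(0L, 1L), n),
    stringsAsFactors = FALSE)
  grid <- expand.grid(acquisition = seq_len(acquisitions_per_container),
                      container = seq_len(containers_per_patient),
                      idx = seq_len(nrow(patients)))
  out <- data.frame(
    patient_id = patients$patient_id[grid$idx],
    label = patients$label[grid$idx],
    container = as.integer(grid$container),
    acquisition = as.integer(grid$acquisition),
    stringsAsFactors = FALSE)
  out$file <- sprintf("%s_c%d_a%d.csv", out$patient_id, out$container,
                      out$acquisition)
  out[, c("file", "patient_id", "label", "container", "acquisition")]
}

#' Featurize every curve of a cohort into labeled instances
#'
#' Reads each acquisition file of a manifest, extracts the 32-parameter
#' feature vector of each of its 32 curves, and attaches the label and full
#' provenance. One instance per curve: a patient with `containers x
#' acquisitions` files contributes `containers x acquisitions x 32`
#' instances.
#'
#' @param manifest a manifest `data.frame` as produced by
#'   [enumerate_cohort()] or [simulate_cohort()].
#' @param dir directory holding the acquisition files.
#' @param circuit a [divider_circuit()] (ppm features depend on it).
#' @param models calibration tables from [sensor_models()].
#' @param on_error `"abort"` (default) stops at the first malformed file with
#'   its path; `"skip"` drops it with a warning and continues.
#' @return instance `data.frame`: the 32 [feature_names()] columns followed
#'   by `label`, `patient_id`, `container`, `acquisition`, `socket`.
#' @export
build_instances <- function(manifest, dir, circuit = divider_circuit(),
                            models = sensor_models(),
                            on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  stopifnot(is.data.frame(manifest), all(c("file", "patient_id", "label",
            "container", "acquisition") %in% names(manifest)))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, manifest$file[i])
    res <- tryCatch({
      curves <- read_acquisition(path)
      feats <- t(vapply(curves, featurize, numeric(32L),
                        circuit = circuit, models = models))
      df <- as.data.frame(feats)
      names(df) <- feature_names()
      df$label <- manifest$label[i]
      df$patient_id <- manifest$patient_id[i]
      df$container <- manifest$container[i]
      df$acquisition <- manifest$acquisition[i]
      df$socket <- 0:31
      df
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- paste0("failed to process ", path, ": ", conditionMessage(res))
      if (on_error == "abort") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      rows[[i]] <- NULL
    } else {
      rows[[i]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Patient-disjoint train/test split
#'
#' Patients — never instances — are randomly assigned to the two sides,
#' stratified by class, so no patient's curves can leak across the split.
#' With the standard design and 10 patients per class per side, each side
#' carries 20 x 640 = 12800 instances.
#'
#' @param instances instance `data.frame` from [build_instances()] or
#'   [read_feature_table()].
#' @param n_per_class_per_side patients of each class on each side
#'   (default 10).
#' @param seed split seed, recorded in the result.
#' @return an object of class `dataset_split`: list with `train`, `test`
#'   (instance data.frames), `split_seed` and the per-side patient ids.
#' @export
split_by_patient <- function(instances, n_per_class_per_side = 10L,
                             seed = 1L) {
  stopifnot(all(c("patient_id", "label") %in% names(instances)))
  pat <- unique(instances[, c("patient_id", "label")])
  picks <- with_seed(seed, {
    lapply(c(0L, 1L), function(cl) {
      ids <- pat$patient_id[pat$label == cl]
      if (length(ids) < 2L * n_per_class_per_side) {
        stop("need at least ", 2L * n_per_class_per_side,
             " patients of class ", cl, ", have ", length(ids), call. = FALSE)
      }
      chosen <- sample(ids, 2L * n_per_class_per_side)
      list(train = chosen[seq_len(n_per_class_per_side)],
           test = chosen[n_per_class_per_side + seq_len(n_per_class_per_side)])
    })
  })
  train_ids <- c(picks[[1L]]$train, picks[[2L]]$train)
  test_ids <- c(picks[[1L]]$test, picks[[2L]]$test)
  structure(list(
    train = instances[instances$patient_id %in% train_ids, , drop = FALSE],
    test = instances[instances$patient_id %in% test_ids, , drop = FALSE],
    train_patients = train_ids, test_patients = test_ids,
    split_seed = as.integer(seed)), class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "<dataset_split> seed %d: %d train instances (%d patients), %d test instances (%d patients)\n",
    x$split_seed, nrow(x$train), length(x$train_patients),
    nrow(x$test), length(x$test_patients)))
  invisible(x)
}

table_columns <- function() {
  c(feature_names(), "label", "patient_id", "container", "acquisition",
    "socket")
}

#' Write / read a feature table
#'
#' CSV with the 32 feature columns in the frozen [feature_names()] order
#' followed by `label,patient_id,container,acquisition,socket`. The reader
#' validates the header and raises a typed `enose_schema_error` on mismatch;
#' write then read is a lossless round trip (to CSV numeric precision).
#'
#' @param instances instance `data.frame` (may have zero rows).
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the instance `data.frame`.
#' @export
write_feature_table <- function(instances, path) {
  missing <- setdiff(table_columns(), names(instances))
  if (length(missing)) {
    schema_error("instance table missing columns: ",
                 paste(missing, collapse = ", "))
  }
  data.table::fwrite(instances[, table_columns(), drop = FALSE], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) schema_error("feature table not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(header, table_columns())) {
    schema_error("feature table header mismatch in ", path)
  }
  dt <- data.table::fread(path, colClasses = list(character = "patient_id"))
  out <- as.data.frame(dt)
  if (nrow(out) == 0L) {
    # fread types empty columns as logical; coerce to the documented schema
    for (nm in setdiff(table_columns(), "patient_id")) out[[nm]] <- numeric(0)
    out$patient_id <- character(0)
    out <- out[, table_columns(), drop = FALSE]
  }
  out
}
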
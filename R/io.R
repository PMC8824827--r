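#' Read and write pedigree files
#'
#' Pedigrees are plain CSV with columns `id`, `kind` (queen, worker_group,
#' sire_group), `dam_id`, `sire_group_id`, `father_dam_id`,
#' `drone_dam_ids` (semicolon-separated list on sire-group rows) and
#' `year`; empty fields mean "none" (base entities). Referential integrity
#' is checked on read and errors cite the offending line.
#'
#' @param path file path.
#' @return `read_pedigree`: a validated pedigree data.frame.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, colClasses = c(
    id = "character", kind = "character", dam_id = "character",
    sire_group_id = "character", father_dam_id = "character",
    drone_dam_ids = "character", year = "integer"), na.strings = "")
  dup <- which(duplicated(ped$id))
  if (length(dup))
    stop("read_pedigree: duplicate id '", ped$id[dup[1]], "' at line ",
         dup[1] + 1L)
  badk <- which(!ped$kind %in% c("queen", "worker_group", "sire_group"))
  if (length(badk))
    stop("read_pedigree: unknown kind '", ped$kind[badk[1]], "' at line ",
         badk[1] + 1L)
  for (cc in c("dam_id", "sire_group_id", "father_dam_id")) {
    ref <- ped[[cc]]
    bad <- which(!is.na(ref) & !ref %in% ped$id)
    if (length(bad))
      stop("read_pedigree: ", cc, " '", ref[bad[1]],
           "' at line ", bad[1] + 1L, " not in file")
  }
  dd <- strsplit(ifelse(is.na(ped$drone_dam_ids), "", ped$drone_dam_ids),
                 ";", fixed = TRUE)
  for (i in seq_along(dd)) {
    miss <- setdiff(dd[[i]][dd[[i]] != ""], ped$id)
    if (length(miss))
      stop("read_pedigree: drone dam '", miss[1], "' at line ", i + 1L,
           " not in file")
  }
  ped
}

#' @rdname read_pedigree
#' @param pedigree pedigree data.frame (e.g. from [simulate_population()]).
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(pedigree[, c("id", "kind", "dam_id", "sire_group_id",
                                "father_dam_id", "drone_dam_ids", "year")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write colony files
#'
#' Colony tables are CSV with columns `colony_id`, `queen_id`,
#' `worker_group_id`, `year`, `apiary`, `phenotype` (empty = missing
#' record) and optionally `a_ww`.
#'
#' @param path file path.
#' @return `read_colonies`: a colony data.frame with numeric phenotypes
#'   (`NA` for missing records).
#' @export
read_colonies <- function(path) {
  col <- utils::read.csv(path, na.strings = "", colClasses = c(
    colony_id = "character", queen_id = "character",
    worker_group_id = "character"))
  for (cc in intersect(c("year", "apiary", "phenotype", "a_ww"),
                       names(col))) {
    v <- col[[cc]]
    if (is.numeric(v) || all(is.na(v))) next
    suppressWarnings(num <- as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("read_colonies: malformed ", cc, " '", v[bad[1]],
           "' at line ", bad[1] + 1L)
    col[[cc]] <- num
  }
  col
}

#' @rdname read_colonies
#' @param colonies colony data.frame.
#' @export
write_colonies <- function(colonies, path) {
  utils::write.csv(colonies, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write genetic truth values
#'
#' @param truth data.frame `id, uQ, uW`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.csv(path, colClasses = c(id = "character"))
}

#' Save and restore a REML fit as JSON
#'
#' The report carries the estimates, predicted standard errors, iteration
#' count, convergence flag and measure, restricted log-likelihood and the
#' failure reason, so a fit can be judged for plausibility after re-reading.
#'
#' @param fit a `reml_fit`.
#' @param path file path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "reml_fit"))
  obj <- fit[c("model", "algorithm", "estimates", "r_AQW", "iterations",
               "converged", "conv_measure", "loglik", "predicted_se",
               "failure")]
  obj$estimates <- as.list(obj$estimates)
  if (!is.null(obj$predicted_se)) obj$predicted_se <- as.list(obj$predicted_se)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  est <- unlist(obj$estimates)
  fit <- list(model = obj$model, algorithm = obj$algorithm,
              estimates = est,
              r_AQW = if (is.null(obj$r_AQW)) NA_real_ else obj$r_AQW,
              iterations = as.integer(obj$iterations),
              converged = isTRUE(obj$converged),
              conv_measure = obj$conv_measure,
              loglik = obj$loglik,
              predicted_se = if (is.null(obj$predicted_se)) NULL else
                unlist(obj$predicted_se),
              failure = obj$failure, trace = NULL, em_monotone = NA)
  class(fit) <- "reml_fit"
  fit
}

#' Write grid results as TSV
#'
#' @param rows data.frame from [run_grid()] / [summarize_fits()].
#' @param path file path.
#' @export
write_results <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a sparse matrix in MatrixMarket coordinate format
#'
#' @param m a (sparse) matrix, e.g. from [a_inverse()].
#' @param path file path.
#' @export
write_matrix_market <- function(m, path) {
  Matrix::writeMM(methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix"),
                  path)
  invisible(path)
}

#' Read a simulation configuration from JSON or YAML
#'
#' The file holds the [sim_config()] fields by name; `trait` is either the
#' name of a standard trait (e.g. `"T3"`) or a mapping with the four
#' components (`sigma2_AQ`, `sigma2_AW`, `sigma_AQW`, `sigma2_E`). Fields
#' not present keep their defaults.
#'
#' @param path file ending in `.json`, `.yml` or `.yaml`.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(obj$trait)) {
    obj$trait <- if (is.character(obj$trait)) {
      std <- bee_traits()
      if (!obj$trait %in% names(std))
        stop("unknown trait name '", obj$trait, "'")
      std[[obj$trait]]
    } else {
      do.call(trait_params, as.list(obj$trait))
    }
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("read_sim_config: unknown field(s): ",
         paste(unknown, collapse = ", "))
  do.call(sim_config, obj)
}
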
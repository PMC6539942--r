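#' Save a fitted model to a diffable directory
#'
#' Writes a [pls1()] or [ctai()] model as plain text: a `model.json` file
#' with scalars and vectors (centering means, y-loadings, coefficients,
#' per-component regression records, angle/bias differences) and CSV files
#' `W.csv` / `P.csv` for the weight and loading matrices, so fitted models
#' can be versioned and inspected.
#'
#' @param object a `"pls1"` or `"ctai"` fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(M, name)
    utils::write.csv(as.data.frame(M),
                     file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  if (inherits(object, "pls1")) {
    meta <- list(type = "pls1", ncomp = object$ncomp,
                 x_mean = object$x_mean, y_mean = object$y_mean,
                 q = object$q, beta = object$beta, rmsec = object$rmsec)
    write_mat(object$W, "W"); write_mat(object$P, "P")
  } else if (inherits(object, "ctai")) {
    meta <- list(type = "ctai", ncomp = object$ncomp,
                 denorm_reference = object$denorm_reference,
                 delta_theta = object$delta_theta,
                 delta_b = object$delta_b,
                 master_regs = object$master_regs,
                 slave_regs = object$slave_regs,
                 master = list(ncomp = object$master$ncomp,
                               x_mean = object$master$x_mean,
                               y_mean = object$master$y_mean,
                               q = object$master$q,
                               beta = object$master$beta,
                               rmsec = object$master$rmsec))
    write_mat(object$master$W, "W"); write_mat(object$master$P, "P")
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a model saved by [save_model()]
#'
#' @param dir directory written by [save_model()].
#' @return The reconstructed `"pls1"` or `"ctai"` object. Training-only
#'   fields (fitted values, residuals) are not serialized and come back as
#'   `NULL`.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  read_mat <- function(name)
    as.matrix(utils::read.csv(file.path(dir, paste0(name, ".csv"))))
  W <- unname(read_mat("W")); P <- unname(read_mat("P"))
  mk_pls <- function(m) {
    structure(list(x_mean = m$x_mean, y_mean = m$y_mean, W = W, P = P,
                   q = m$q, beta = m$beta, ncomp = as.integer(m$ncomp),
                   rmsec = m$rmsec, fitted.values = NULL,
                   residuals = NULL), class = "pls1")
  }
  if (meta$type == "pls1") return(mk_pls(meta))
  if (meta$type == "ctai") {
    regs <- function(df) lapply(seq_len(nrow(df)), function(i)
      as.list(df[i, ]))
    return(structure(list(master = mk_pls(meta$master),
                          master_regs = regs(meta$master_regs),
                          slave_regs = regs(meta$slave_regs),
                          delta_theta = meta$delta_theta,
                          delta_b = meta$delta_b,
                          ncomp = as.integer(meta$ncomp),
                          denorm_reference = meta$denorm_reference),
                     class = "ctai"))
  }
  stop("unknown model type: ", meta$type, call. = FALSE)
}
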
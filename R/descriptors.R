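#' Assemble field blocks into a PLS descriptor matrix
#'
#' Concatenates the per-kind field blocks column-wise, dropping columns
#' whose standard deviation across molecules falls below a per-kind
#' minimum-sigma threshold, then (optionally) applies block-standard
#' ("CoMFA-STD") scaling: each surviving block is divided by one
#' block-wide standard deviation so that no field dominates the regression
#' purely by its numeric scale. The returned object records everything
#' needed to map any column back to its lattice point (for contouring) and
#' to project a new set of molecules onto the same columns and scales (for
#' external prediction).
#'
#' @param blocks Named list of `field_block`s sharing molecule order and
#'   lattice.
#' @param scaling `"comfa_std"` or `"none"`.
#' @param min_sigma Single number, or named per-kind vector, of
#'   minimum-sigma thresholds (kcal/mol for CoMFA kinds, unitless for
#'   CoMSIA). Default: 2.0 for the CoMFA energy blocks, 0 for CoMSIA.
#' @return Object of class `descriptor_set`: `X` (molecules x columns),
#'   `index` (data.frame `kind`, `point`, column per row), `block_scale`
#'   (named divisors), `scaling`, `min_sigma`.
#' @export
assemble_descriptors <- function(blocks, scaling = c("comfa_std", "none"),
                                 min_sigma = NULL) {
  scaling <- match.arg(scaling)
  kinds <- names(blocks)
  if (is.null(kinds) || !length(kinds)) stop("no field blocks supplied")
  nmol <- nrow(blocks[[1]]$values)
  for (b in blocks)
    if (nrow(b$values) != nmol) stop("blocks disagree on molecule count")
  sig <- .min_sigma_per_kind(kinds, min_sigma)
  Xs <- list(); idx <- list(); scales <- stats::setNames(rep(1, length(kinds)), kinds)
  keep_list <- stats::setNames(vector("list", length(kinds)), kinds)
  for (k in kinds) {
    V <- blocks[[k]]$values
    sds <- .col_sds(V)
    keep <- which(sds >= sig[k] & is.finite(sds))
    keep_list[[k]] <- keep
    if (!length(keep)) next
    Vk <- V[, keep, drop = FALSE]
    if (scaling == "comfa_std") {
      s <- stats::sd(as.vector(Vk))
      if (is.finite(s) && s > 0) { Vk <- Vk / s; scales[k] <- s }
    }
    Xs[[k]] <- Vk
    idx[[k]] <- data.frame(kind = k, point = keep, stringsAsFactors = FALSE)
  }
  if (!length(Xs)) stop("no descriptor columns survive the min-sigma filter")
  X <- do.call(cbind, Xs)
  index <- do.call(rbind, idx)
  rownames(index) <- NULL
  index$column <- seq_len(nrow(index))
  structure(list(X = X, index = index, block_scale = scales,
                 scaling = scaling, min_sigma = sig, kept = keep_list),
            class = "descriptor_set")
}

.min_sigma_per_kind <- function(kinds, min_sigma) {
  default <- ifelse(startsWith(kinds, "comfa"), 2.0, 0.0)
  names(default) <- kinds
  if (is.null(min_sigma)) return(default)
  if (length(min_sigma) == 1L && is.null(names(min_sigma)))
    return(stats::setNames(rep(min_sigma, length(kinds)), kinds))
  default[names(min_sigma)] <- min_sigma
  default
}

#' Project new molecules onto an existing descriptor set
#'
#' Applies the column selection and block scales learned by
#' [assemble_descriptors()] on the training series to field blocks computed
#' for new molecules on the same lattice — the external-test-set path.
#'
#' @param dset A `descriptor_set`.
#' @param blocks Named list of `field_block`s for the new molecules (same
#'   lattice, same kinds).
#' @return Descriptor matrix with columns matching `dset$X`.
#' @export
project_descriptors <- function(dset, blocks) {
  Xs <- list()
  for (k in names(dset$kept)) {
    keep <- dset$kept[[k]]
    if (!length(keep)) next
    if (is.null(blocks[[k]])) stop("missing field block for kind ", k)
    Vk <- blocks[[k]]$values[, keep, drop = FALSE] / dset$block_scale[k]
    Xs[[k]] <- Vk
  }
  do.call(cbind, Xs)
}
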
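#' @include AllClasses.R AllGenerics.R
NULL

#' Read and write screen tensors as long-format TSV
#'
#' The interchange format is a long table with columns \code{target_gene},
#' \code{target_design}, \code{query_gene}, \code{query_design},
#' \code{feature}, \code{value}; designs are 1 or 2. Cells absent from the
#' file become missing values.
#'
#' @param path file path.
#' @param transformed whether the values are on the variance-stabilised
#'   scale (stored in the returned object).
#' @return \code{readScreenTensor} returns a \linkS4class{ScreenTensor}.
#' @export
readScreenTensor <- function(path, transformed = FALSE) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("target_gene", "target_design", "query_gene", "query_design",
            "feature", "value")
  if (!all(need %in% names(tb)))
    stop("expected columns: ", paste(need, collapse = ", "))
  tg <- sort(unique(tb$target_gene)); qg <- sort(unique(tb$query_gene))
  feats <- unique(tb$feature)
  if (!all(tb$target_design %in% 1:2) || !all(tb$query_design %in% 1:2))
    stop("designs must be 1 or 2")
  v <- array(NA_real_, c(length(tg), 2L, length(qg), 2L, length(feats)),
             dimnames = list(tg, c("ds1", "ds2"), qg, c("ds1", "ds2"),
                             feats))
  v[cbind(match(tb$target_gene, tg), tb$target_design,
          match(tb$query_gene, qg), tb$query_design,
          match(tb$feature, feats))] <- tb$value
  ScreenTensor(values = v, transformed = transformed)
}

#' @rdname readScreenTensor
#' @param tensor a \linkS4class{ScreenTensor}.
#' @export
writeScreenTensor <- function(tensor, path) {
  stopifnot(is(tensor, "ScreenTensor"))
  v <- tensor@values
  d <- dim(v); dn <- dimnames(v)
  grid <- expand.grid(target_gene = dn[[1L]], target_design = 1:2,
                      query_gene = dn[[3L]], query_design = 1:2,
                      feature = dn[[5L]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$value <- as.vector(v)
  grid <- grid[!is.na(grid$value), ]
  utils::write.table(grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
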
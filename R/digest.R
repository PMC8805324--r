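#' Cross-language fingerprint of a container
#'
#' Computes the same structural digest of an in-memory `MuContainer` that
#' `inst/python/h5mu_digest.py` computes from a `.h5mu` file with h5py:
#' modality order, axis names, annotation columns with full values and
#' missing positions, matrix checksums and axis maps. Comparing the two
#' digests verifies that the on-disk dialect is decodable outside R with
#' identical content.
#'
#' @param mc a `MuContainer`.
#' @return A nested list mirroring the Python digest (JSON-comparable
#'   after `jsonlite` round-trip).
#' @export
container_digest <- function(mc) {
  list(
    encoding_type = "MuData",
    mod_order = as.list(names(mc$mod)),
    obs = digest_df(mc$obs),
    var = digest_df(mc$var),
    obsmap = lapply(mc$obsmap, as.list),
    varmap = lapply(mc$varmap, as.list),
    mod = lapply(mc$mod, function(am) {
      list(X = digest_matrix(am$X),
           obs = digest_df(am$obs),
           var = digest_df(am$var),
           layers = {
             nms <- sort(names(am$layers))
             stats::setNames(lapply(nms, function(nm) digest_matrix(am$layers[[nm]])), nms)
           })
    }))
}

digest_df <- function(df) {
  list(index = as.list(rownames(df)),
       columns = stats::setNames(lapply(colnames(df), function(cl) digest_column(df[[cl]])),
                                 colnames(df)),
       column_order = as.list(colnames(df)))
}

digest_column <- function(v) {
  boxed <- function(x, f) lapply(seq_along(x), function(i)
    if (is.na(x[i])) NULL else f(x[i]))
  if (is.factor(v)) {
    list(kind = "categorical", categories = as.list(levels(v)),
         values = boxed(as.character(v), identity))
  } else if (is.logical(v)) {
    list(kind = "boolean", values = boxed(v, identity))
  } else if (is.integer(v)) {
    list(kind = "integer", values = boxed(v, as.integer))
  } else if (is.character(v)) {
    list(kind = "string", values = as.list(v))
  } else {
    list(kind = "float", values = boxed(v, function(x) round(x, 10)))
  }
}

digest_matrix <- function(m) {
  m <- materialize(m)
  if (inherits(m, "sparseMatrix")) {
    r <- methods::as(methods::as(m, "generalMatrix"), "RsparseMatrix")
    list(kind = "csr", shape = as.list(dim(r)), nnz = length(r@x),
         sum = round(sum(r@x), 10), indices_sum = sum(r@j),
         indptr_last = r@p[length(r@p)])
  } else {
    m <- as.matrix(m)
    flat <- as.vector(t(m))                     # C-order, as h5py sees it
    list(kind = "dense", shape = as.list(dim(m)),
         sum = round(sum(flat, na.rm = TRUE), 10),
         first_row = as.list(round(flat[seq_len(min(10, length(flat)))], 10)))
  }
}
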
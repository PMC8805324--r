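#' Deep equality of containers and modalities
#'
#' Structural comparison used for serialisation round-trip checks: slot
#' names and order, modality order, axis names, matrix classes (dense vs
#' row-sparse) and exact values, annotation column types, factor levels
#' and order, missing-value positions, axis maps and unstructured
#' metadata must all agree. Matrix dimnames are not compared — axis names
#' are owned by the annotation tables.
#'
#' @param a,b two `MuContainer` objects (or two [AnnotatedMatrix()] for
#'   `annmatrix_equal`).
#' @return `TRUE`, or a character scalar describing the first difference.
#' @export
container_equal <- function(a, b) {
  if (!inherits(a, "MuContainer") || !inherits(b, "MuContainer"))
    return("not MuContainer objects")
  if (!identical(names(a$mod), names(b$mod)))
    return(sprintf("modality names differ: [%s] vs [%s]",
                   paste(names(a$mod), collapse = ","), paste(names(b$mod), collapse = ",")))
  for (m in names(a$mod)) {
    r <- annmatrix_equal(a$mod[[m]], b$mod[[m]])
    if (!isTRUE(r)) return(sprintf("modality '%s': %s", m, r))
  }
  for (slot in c("obs", "var")) {
    r <- df_equal(a[[slot]], b[[slot]])
    if (!isTRUE(r)) return(sprintf("global %s: %s", slot, r))
  }
  for (slot in c("obsm", "varm", "obsp", "varp")) {
    r <- mapping_equal(a[[slot]], b[[slot]])
    if (!isTRUE(r)) return(sprintf("global %s: %s", slot, r))
  }
  for (slot in c("obsmap", "varmap")) {
    if (!identical(lapply(a[[slot]], as.integer), lapply(b[[slot]], as.integer)))
      return(sprintf("%s differs", slot))
  }
  r <- uns_equal(a$uns, b$uns)
  if (!isTRUE(r)) return(sprintf("global uns: %s", r))
  TRUE
}

#' @rdname container_equal
#' @export
annmatrix_equal <- function(a, b) {
  r <- mat_equal(a$X, b$X); if (!isTRUE(r)) return(sprintf("X: %s", r))
  for (slot in c("obs", "var")) {
    r <- df_equal(a[[slot]], b[[slot]])
    if (!isTRUE(r)) return(sprintf("%s: %s", slot, r))
  }
  if (!setequal(name_vec(a$layers), name_vec(b$layers)) ||
      length(a$layers) != length(b$layers)) return("layer names differ")
  for (nm in names(a$layers)) {
    r <- mat_equal(a$layers[[nm]], b$layers[[nm]])
    if (!isTRUE(r)) return(sprintf("layer '%s': %s", nm, r))
  }
  for (slot in c("obsm", "varm", "obsp", "varp")) {
    r <- mapping_equal(a[[slot]], b[[slot]])
    if (!isTRUE(r)) return(sprintf("%s: %s", slot, r))
  }
  r <- uns_equal(a$uns, b$uns)
  if (!isTRUE(r)) return(sprintf("uns: %s", r))
  TRUE
}

name_vec <- function(x) if (is.null(names(x))) character(length(x)) else names(x)

mat_equal <- function(a, b) {
  a <- materialize(a); b <- materialize(b)
  a_sparse <- inherits(a, "sparseMatrix"); b_sparse <- inherits(b, "sparseMatrix")
  if (a_sparse != b_sparse) return("sparse/dense mismatch")
  if (!identical(as.integer(dim(a)), as.integer(dim(b))))
    return(sprintf("shape %s vs %s", paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  if (a_sparse) {
    a <- methods::as(methods::as(a, "generalMatrix"), "RsparseMatrix")
    b <- methods::as(methods::as(b, "generalMatrix"), "RsparseMatrix")
    if (!identical(a@p, b@p) || !identical(a@j, b@j) || !identical(a@x, b@x))
      return("sparse values differ")
    return(TRUE)
  }
  ua <- a; ub <- b; dimnames(ua) <- NULL; dimnames(ub) <- NULL
  if (typeof(ua) != typeof(ub)) return(sprintf("storage %s vs %s", typeof(ua), typeof(ub)))
  if (!identical(ua, ub)) return("dense values differ")
  TRUE
}

df_equal <- function(a, b) {
  if (!identical(rownames(a), rownames(b))) return("index differs")
  if (!identical(colnames(a), colnames(b)))
    return(sprintf("columns differ: [%s] vs [%s]",
                   paste(colnames(a), collapse = ","), paste(colnames(b), collapse = ",")))
  for (cl in colnames(a)) {
    x <- a[[cl]]; y <- b[[cl]]
    if (is.factor(x) != is.factor(y)) return(sprintf("column '%s': categorical vs not", cl))
    if (is.factor(x)) {
      if (!identical(levels(x), levels(y))) return(sprintf("column '%s': levels differ", cl))
      if (is.ordered(x) != is.ordered(y)) return(sprintf("column '%s': orderedness differs", cl))
      if (!identical(as.integer(x), as.integer(y))) return(sprintf("column '%s': codes differ", cl))
    } else {
      if (typeof(x) != typeof(y))
        return(sprintf("column '%s': type %s vs %s", cl, typeof(x), typeof(y)))
      if (!identical(unname(x), unname(y))) return(sprintf("column '%s': values differ", cl))
    }
  }
  TRUE
}

# named slots are maps: HDF5 groups carry no insertion order, so entry
# order is not significant — name sets must agree exactly.
mapping_equal <- function(a, b) {
  if (!setequal(name_vec(a), name_vec(b)) || length(a) != length(b))
    return(sprintf("entry names differ: [%s] vs [%s]",
                   paste(names(a), collapse = ","), paste(names(b), collapse = ",")))
  for (nm in names(a)) {
    r <- mat_equal(a[[nm]], b[[nm]])
    if (!isTRUE(r)) return(sprintf("entry '%s': %s", nm, r))
  }
  TRUE
}

uns_equal <- function(a, b) {
  if (is.list(a) != is.list(b)) return("nesting differs")
  if (is.list(a)) {
    if (!setequal(name_vec(a), name_vec(b)) || length(a) != length(b))
      return(sprintf("keys differ: [%s] vs [%s]",
                     paste(names(a), collapse = ","), paste(names(b), collapse = ",")))
    for (nm in names(a)) {
      r <- uns_equal(a[[nm]], b[[nm]])
      if (!isTRUE(r)) return(sprintf("%s: %s", nm, r))
    }
    return(TRUE)
  }
  if (is.matrix(a) || is.matrix(b) || inherits(a, "sparseMatrix") || inherits(b, "sparseMatrix"))
    return(mat_equal(a, b))
  if (is.factor(a) != is.factor(b)) return("categorical vs not")
  if (is.factor(a)) {
    if (!identical(levels(a), levels(b)) || !identical(as.integer(a), as.integer(b)))
      return("categorical values differ")
    return(TRUE)
  }
  if (typeof(a) != typeof(b)) return(sprintf("type %s vs %s", typeof(a), typeof(b)))
  if (!identical(unname(a), unname(b))) return("values differ")
  TRUE
}
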
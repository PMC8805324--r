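#' Multimodal container with union-of-observations semantics
#'
#' A `MuContainer` is an ordered collection of named [AnnotatedMatrix()]
#' modalities sharing a pair of *global* axes:
#'
#' * the global observation axis is the union of the modalities'
#'   observation names, in first-seen order scanning modalities in insertion
#'   order — a cell may be present in only some modalities;
#' * the global feature axis is the concatenation of the modalities' feature
#'   names in modality order; names colliding across modalities are
#'   disambiguated as `"modality:name"` in the global table only.
#'
#' Per-modality integer *axis maps* (`obsmap`, `varmap`) align the global
#' axes to each modality: entry `k > 0` means the global element is local
#' row/column `k` of that modality, `0` means absent. Axis maps are kept
#' order-preserving: during [mu_update()] each modality's rows are stably
#' reordered so that they appear in global order, which makes every map's
#' nonzero subsequence strictly increasing.
#'
#' The container also carries global annotation tables (`obs`, `var`),
#' global embedding/pairwise/unstructured slots (`obsm`, `varm`, `obsp`,
#' `varp`, `uns`) aligned to the global axes.
#'
#' @param mods named list of [AnnotatedMatrix()] objects (at least one;
#'   names must be unique and non-empty).
#' @return A `MuContainer` with global axes and axis maps computed.
#' @examples
#' rna <- AnnotatedMatrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("c1", "c2", "c3"), c("g1", "g2"))))
#' atac <- AnnotatedMatrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("c2", "c3", "c4"), c("p1", "p2"))))
#' mc <- make_container(list(rna = rna, atac = atac))
#' obs_names(mc)          # c1 c2 c3 c4
#' mc$obsmap$atac         # 0 1 2 3
#' @export
make_container <- function(mods) {
  if (!is.list(mods) || length(mods) < 1L)
    stop("mods must be a non-empty named list of AnnotatedMatrix objects")
  nm <- names(mods)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every modality must be named")
  if (anyDuplicated(nm))
    stop(sprintf("duplicate modality names: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  for (i in seq_along(mods)) {
    if (!inherits(mods[[i]], "AnnotatedMatrix"))
      stop(sprintf("modality '%s' is not an AnnotatedMatrix", nm[i]))
    validate_annmatrix(mods[[i]], nm[i])
  }
  mc <- structure(
    list(mod = mods,
         obs = data.frame(), var = data.frame(),
         obsm = list(), varm = list(), obsp = list(), varp = list(),
         uns = list(), obsmap = list(), varmap = list(),
         pulled = list(obs = character(), var = character())),
    class = "MuContainer", stale = TRUE)
  mu_update(mc)
}

#' @export
dim.MuContainer <- function(x) c(nrow(x$obs), nrow(x$var))

#' @export
obs_names.MuContainer <- function(x) rownames(x$obs)

#' @export
var_names.MuContainer <- function(x) rownames(x$var)

#' Names of the modalities in a container
#' @param x a `MuContainer`.
#' @return Character vector of modality names in insertion order.
#' @export
modality_names <- function(x) names(x$mod)

#' Is a container stale (global axes out of date)?
#'
#' Mutating a modality in place ([set_modality()] / [del_modality()]) does
#' not silently recompute the global axes; the container is flagged stale
#' and axis-dependent operations refuse to run until [mu_update()].
#' @param x a `MuContainer`.
#' @return `TRUE` if [mu_update()] must be called before axis-dependent use.
#' @export
is_stale <- function(x) isTRUE(attr(x, "stale"))

stop_if_stale <- function(x) {
  if (is_stale(x))
    stop("container is stale after modality mutation; call mu_update() first")
  invisible(x)
}

# global var names under the collision rule: names present in >1 modality
# get a "modality:" prefix in the global table only.
global_var_names <- function(mods) {
  per <- lapply(mods, var_names)
  all <- unlist(per, use.names = FALSE)
  colliding <- unique(all[duplicated(all)])
  unlist(lapply(names(mods), function(m) {
    v <- per[[m]]
    ifelse(v %in% colliding, paste0(m, ":", v), v)
  }), use.names = FALSE)
}

# carry user columns of an annotation table onto a new index
carry_columns <- function(old, new_names, drop_cols = character()) {
  out <- data.frame(row.names = new_names)
  keep <- setdiff(colnames(old), drop_cols)
  idx <- match(new_names, rownames(old))
  for (cl in keep) out[[cl]] <- old[[cl]][idx]
  out
}

#' Recompute global axes, axis maps and pulled annotation columns
#'
#' Rebuilds the global observation axis (first-seen union), the global
#' feature axis (modality-order concatenation with collision
#' disambiguation) and all axis maps from the current modalities. User
#' columns of the global tables are preserved for surviving names (missing
#' for new names); every modality annotation column is pulled into the
#' global table under `"modality:column"`, with missing markers where the
#' element is absent from the modality. Idempotent.
#'
#' @param mc a `MuContainer`.
#' @return The updated container (stale flag cleared).
#' @export
mu_update <- function(mc) {
  stopifnot(inherits(mc, "MuContainer"))
  if (length(mc$mod) < 1L) stop("container must keep at least one modality")
  for (m in names(mc$mod)) validate_annmatrix(mc$mod[[m]], m)

  # ---- observations: first-seen union; reorder modality rows to global order
  gl_obs <- character()
  for (m in names(mc$mod))
    gl_obs <- c(gl_obs, setdiff(obs_names(mc$mod[[m]]), gl_obs))
  for (m in names(mc$mod)) {
    loc <- obs_names(mc$mod[[m]])
    perm <- order(match(loc, gl_obs))
    if (!identical(perm, seq_along(loc)))
      mc$mod[[m]] <- subset_annmatrix(mc$mod[[m]], i = perm)
  }
  mc$obsmap <- lapply(mc$mod, function(am) {
    k <- match(gl_obs, obs_names(am))
    k[is.na(k)] <- 0L
    as.integer(k)
  })

  # ---- features: concatenation with collision prefix
  gl_var <- global_var_names(mc$mod)
  offsets <- cumsum(c(0L, vapply(mc$mod, function(am) nrow(am$var), 0L)))
  mc$varmap <- stats::setNames(lapply(seq_along(mc$mod), function(i) {
    k <- integer(length(gl_var))
    d <- nrow(mc$mod[[i]]$var)
    if (d > 0) k[offsets[i] + seq_len(d)] <- seq_len(d)
    k
  }), names(mc$mod))

  # ---- global tables: preserve user columns, refresh pulled columns
  obs <- carry_columns(mc$obs, gl_obs, drop_cols = mc$pulled$obs)
  var <- carry_columns(mc$var, gl_var, drop_cols = mc$pulled$var)
  pulled_obs <- character(); pulled_var <- character()
  for (m in names(mc$mod)) {
    am <- mc$mod[[m]]
    map <- mc$obsmap[[m]]
    for (cl in colnames(am$obs)) {
      tgt <- paste0(m, ":", cl)
      obs[[tgt]] <- pulled_values(am$obs[[cl]], map)
      pulled_obs <- c(pulled_obs, tgt)
    }
    vmap <- mc$varmap[[m]]
    for (cl in colnames(am$var)) {
      tgt <- paste0(m, ":", cl)
      var[[tgt]] <- pulled_values(am$var[[cl]], vmap)
      pulled_var <- c(pulled_var, tgt)
    }
  }
  mc$pulled <- list(obs = pulled_obs, var = pulled_var)

  # ---- global aligned slots: keep only if the axis is unchanged
  if (!identical(gl_obs, rownames(mc$obs))) {
    mc$obsm <- align_rows(mc$obsm, rownames(mc$obs), gl_obs)
    mc$obsp <- align_square(mc$obsp, rownames(mc$obs), gl_obs)
  }
  if (!identical(gl_var, rownames(mc$var))) {
    mc$varm <- align_rows(mc$varm, rownames(mc$var), gl_var)
    mc$varp <- align_square(mc$varp, rownames(mc$var), gl_var)
  }
  mc$obs <- obs
  mc$var <- var
  attr(mc, "stale") <- FALSE
  mc
}

# column values mapped onto a global axis via an axis map (0 = absent -> NA)
pulled_values <- function(v, map) {
  idx <- ifelse(map > 0L, map, NA_integer_)
  if (is.factor(v)) {
    factor(levels(v)[as.integer(v)[idx]], levels = levels(v),
           ordered = is.ordered(v))
  } else v[idx]
}

align_rows <- function(slots, old_names, new_names) {
  idx <- match(new_names, old_names)
  lapply(slots, function(m) {
    out <- m[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    out[is.na(idx), ] <- NA
    rownames(out) <- NULL
    out
  })
}

align_square <- function(slots, old_names, new_names) {
  idx <- match(new_names, old_names)
  keep <- !is.na(idx)
  lapply(slots, function(m) {
    n <- length(new_names)
    out <- matrix(0, n, n)
    out[keep, keep] <- as.matrix(m)[idx[keep], idx[keep]]
    out
  })
}

# resolve a selector (logical mask / integer positions / names) to integer
# positions over an axis; duplicates and unknowns are rejected.
resolve_selector <- function(sel, axis_names, axis = "obs") {
  n <- length(axis_names)
  if (is.null(sel)) return(seq_len(n))
  if (is.logical(sel)) {
    if (length(sel) != n)
      stop(sprintf("logical %s selector has length %d, axis has %d", axis, length(sel), n))
    return(which(sel))
  }
  if (is.numeric(sel)) {
    sel <- as.integer(sel)
    if (any(sel < 1L | sel > n))
      stop(sprintf("%s selector positions out of range [1, %d]: %s", axis, n,
                   paste(utils::head(sel[sel < 1L | sel > n], 10L), collapse = ", ")))
    if (anyDuplicated(sel))
      stop(sprintf("duplicated positions in %s selector", axis))
    return(sel)
  }
  if (is.character(sel)) {
    if (anyDuplicated(sel))
      stop(sprintf("duplicated names in %s selector", axis))
    idx <- match(sel, axis_names)
    if (anyNA(idx))
      stop(sprintf("unknown %s names: %s", axis,
                   paste(utils::head(sel[is.na(idx)], 10L), collapse = ", ")))
    return(idx)
  }
  stop(sprintf("unsupported %s selector of class %s", axis, class(sel)[1L]))
}

#' Subset a container along its global axes
#'
#' Observations are selected in every modality as well as in the global
#' annotation slots; features from different modalities can be combined
#' freely. Each modality keeps exactly its members among the selected
#' global elements, in selected order; axis maps are recomputed. Modalities
#' reduced to zero observations or features are kept (empty), not dropped.
#'
#' The global observation axis of the result follows the selector's order;
#' the global feature axis remains the concatenation of per-modality blocks
#' in modality order.
#'
#' @param x a `MuContainer` (not stale).
#' @param obs,var selector over the respective global axis: a logical mask,
#'   integer positions, character names, or `NULL` (keep all). Unknown
#'   names, out-of-range positions and duplicated entries are rejected.
#' @param ... ignored (S3 signature compatibility).
#' @return A new `MuContainer`.
#' @export
subset.MuContainer <- function(x, obs = NULL, var = NULL, ...) {
  stop_if_stale(x)
  osel <- resolve_selector(obs, rownames(x$obs), "obs")
  vsel <- resolve_selector(var, rownames(x$var), "var")

  # feature selection: regroup into per-modality blocks (modality order)
  vsel_blocks <- lapply(names(x$mod), function(m) vsel[x$varmap[[m]][vsel] > 0L])
  names(vsel_blocks) <- names(x$mod)
  vsel_global <- unlist(vsel_blocks, use.names = FALSE)

  out <- x
  for (m in names(x$mod)) {
    loc_i <- x$obsmap[[m]][osel]
    loc_j <- x$varmap[[m]][vsel_blocks[[m]]]
    out$mod[[m]] <- subset_annmatrix(x$mod[[m]], i = loc_i[loc_i > 0L], j = loc_j)
    omap <- integer(length(osel))
    omap[loc_i > 0L] <- seq_len(sum(loc_i > 0L))
    out$obsmap[[m]] <- omap
  }
  offsets <- cumsum(c(0L, vapply(vsel_blocks, length, 0L)))
  out$varmap <- stats::setNames(lapply(seq_along(x$mod), function(i) {
    k <- integer(length(vsel_global))
    d <- length(vsel_blocks[[i]])
    if (d > 0) k[offsets[i] + seq_len(d)] <- seq_len(d)
    k
  }), names(x$mod))

  out$obs <- x$obs[osel, , drop = FALSE]
  out$var <- x$var[vsel_global, , drop = FALSE]
  out$obsm <- lapply(x$obsm, function(m) m[osel, , drop = FALSE])
  out$obsp <- lapply(x$obsp, function(m) m[osel, osel, drop = FALSE])
  out$varm <- lapply(x$varm, function(m) m[vsel_global, , drop = FALSE])
  out$varp <- lapply(x$varp, function(m) m[vsel_global, vsel_global, drop = FALSE])
  out
}

#' Restrict a container to observations present in every modality
#'
#' Complements the union semantics: keeps exactly the global observations
#' whose axis map is nonzero in all modalities, preserving order. An empty
#' intersection yields a valid zero-observation container with a warning.
#'
#' @param mc a `MuContainer`.
#' @return A new `MuContainer`.
#' @export
intersect_obs <- function(mc) {
  stop_if_stale(mc)
  present <- Reduce(`&`, lapply(mc$obsmap, function(m) m > 0L))
  if (!any(present))
    warning("intersection of observations across modalities is empty")
  subset(mc, obs = which(present))
}

#' Copy global observation columns into every modality
#'
#' Each named column of the global `obs` table is copied into each
#' modality's `obs`, restricted through the axis map to the cells the
#' modality contains.
#'
#' @param mc a `MuContainer` (not stale).
#' @param columns character vector of global `obs` column names.
#' @param overwrite overwrite existing modality columns of the same name?
#' @return The modified container.
#' @export
push_obs <- function(mc, columns, overwrite = FALSE) {
  stop_if_stale(mc)
  missing_cols <- setdiff(columns, colnames(mc$obs))
  if (length(missing_cols))
    stop(sprintf("global obs columns not found: %s", paste(missing_cols, collapse = ", ")))
  for (m in names(mc$mod)) {
    map <- mc$obsmap[[m]]
    sel <- which(map > 0L)            # global positions present in m
    for (cl in columns) {
      if (cl %in% colnames(mc$mod[[m]]$obs) && !overwrite)
        stop(sprintf("column '%s' already exists in modality '%s' (set overwrite = TRUE)", cl, m))
      v <- mc$obs[[cl]][sel]
      mc$mod[[m]]$obs[[cl]] <- v[order(map[sel])]  # local order
    }
  }
  mc
}

#' Copy modality observation columns into the global table
#'
#' A modality column `col` becomes global column `"modality:col"`, with
#' missing markers at observations absent from that modality.
#'
#' @param mc a `MuContainer` (not stale).
#' @param mod modality name.
#' @param columns character vector of that modality's `obs` column names.
#' @param overwrite overwrite an existing global column of the same name?
#' @return The modified container.
#' @export
pull_obs <- function(mc, mod, columns, overwrite = FALSE) {
  stop_if_stale(mc)
  if (!mod %in% names(mc$mod))
    stop(sprintf("unknown modality '%s' (available: %s)", mod,
                 paste(names(mc$mod), collapse = ", ")))
  am <- mc$mod[[mod]]
  missing_cols <- setdiff(columns, colnames(am$obs))
  if (length(missing_cols))
    stop(sprintf("columns not in modality '%s' obs: %s", mod,
                 paste(missing_cols, collapse = ", ")))
  for (cl in columns) {
    tgt <- paste0(mod, ":", cl)
    if (tgt %in% colnames(mc$obs) && !overwrite && !tgt %in% mc$pulled$obs)
      stop(sprintf("global column '%s' already exists (set overwrite = TRUE)", tgt))
    mc$obs[[tgt]] <- pulled_values(am$obs[[cl]], mc$obsmap[[mod]])
    mc$pulled$obs <- union(mc$pulled$obs, tgt)
  }
  mc
}

#' Add or replace a modality / delete a modality
#'
#' The modality mapping is updated and the container flagged stale: global
#' axes are not silently recomputed, call [mu_update()].
#'
#' @param mc a `MuContainer`.
#' @param name modality name (a valid non-empty identifier for `set`).
#' @param am an [AnnotatedMatrix()].
#' @return The modified (stale) container.
#' @export
set_modality <- function(mc, name, am) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("modality name must be a single non-empty string")
  if (!inherits(am, "AnnotatedMatrix")) stop("am must be an AnnotatedMatrix")
  validate_annmatrix(am, name)
  mc$mod[[name]] <- am
  attr(mc, "stale") <- TRUE
  mc
}

#' @rdname set_modality
#' @export
del_modality <- function(mc, name) {
  if (!name %in% names(mc$mod))
    stop(sprintf("unknown modality '%s' (available: %s)", name,
                 paste(names(mc$mod), collapse = ", ")))
  if (length(mc$mod) == 1L)
    stop("cannot delete the last modality: a container keeps at least one")
  mc$mod[[name]] <- NULL
  attr(mc, "stale") <- TRUE
  mc
}

#' @export
print.MuContainer <- function(x, ...) {
  cat(sprintf("MuContainer  %d obs x %d var, %d modalit%s%s\n",
              nrow(x$obs), nrow(x$var), length(x$mod),
              if (length(x$mod) == 1L) "y" else "ies",
              if (is_stale(x)) "  [stale]" else ""))
  for (m in names(x$mod))
    cat(sprintf("  mod '%s': %d x %d\n", m, nrow(x$mod[[m]]$obs), nrow(x$mod[[m]]$var)))
  for (slot in c("obsm", "varm", "obsp", "varp", "uns")) {
    nm <- names(x[[slot]])
    if (length(nm)) cat(sprintf("  %s: %s\n", slot, paste(nm, collapse = ", ")))
  }
  invisible(x)
}
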
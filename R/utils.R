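#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state on exit.
# All stochastic operations in the package route through this so that every
# exported function is a pure function of (arguments, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of one user-facing seed into named child seeds.
# Children are drawn from a stream seeded by the parent, in the order of
# `names`, so adding a component at the end never changes earlier children.
derive_seeds <- function(seed, names) {
  kids <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(names)))
  stats::setNames(as.integer(kids), names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared argument checks ------------------------------------------------------

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# A morphometric table is a numeric subjects x regions matrix with subject ids
# as rownames, region ids as colnames, and a "measure" attribute
# ("thickness", "area" or "volume").
assert_morph_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("morphometric table must be a numeric matrix (subjects x regions)",
         call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("morphometric table needs subject rownames and region colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate subject ids in morphometric table", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("morphometric table contains non-finite values", call. = FALSE)
  }
  invisible(values)
}

assert_metadata <- function(meta, n_subjects = NULL) {
  if (!is.data.frame(meta)) stop("metadata must be a data.frame", call. = FALSE)
  need <- c("subject_id", "site", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyNA(meta$site) || anyNA(meta$group)) {
    stop("every subject must have a site and a group", call. = FALSE)
  }
  if (!is.null(n_subjects) && nrow(meta) != n_subjects) {
    stop("metadata rows do not match morphometric table subjects",
         call. = FALSE)
  }
  invisible(meta)
}

# Align metadata rows to the subject order of a table.
align_meta <- function(values, meta) {
  assert_metadata(meta)
  idx <- match(rownames(values), meta$subject_id)
  if (anyNA(idx)) {
    stop("subjects missing from metadata: ",
         paste(utils::head(rownames(values)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  meta[idx, , drop = FALSE]
}

# Build a covariate design matrix (without intercept column) from metadata,
# erroring informatively on rank deficiency.
covariate_design <- function(meta, covariates, interactions = character()) {
  if (length(covariates) == 0L && length(interactions) == 0L) {
    return(matrix(numeric(0), nrow = nrow(meta), ncol = 0))
  }
  miss <- setdiff(covariates, names(meta))
  if (length(miss)) {
    stop("covariate(s) not in metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  terms <- c(covariates, interactions)
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  df <- meta[, unique(unlist(strsplit(covariates, ":"))), drop = FALSE]
  for (ii in interactions) {
    for (v in strsplit(ii, ":")[[1]]) {
      if (!v %in% names(df)) df[[v]] <- meta[[v]]
    }
  }
  chr <- vapply(df, is.character, logical(1))
  df[chr] <- lapply(df[chr], factor)
  X <- stats::model.matrix(fml, data = df)
  X[, -1, drop = FALSE]
}

check_full_rank <- function(X, context = "design matrix") {
  if (ncol(X) == 0L) return(invisible(TRUE))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("%s is rank deficient; collinear column(s): %s",
                 context, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
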
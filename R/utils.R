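`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a numeric design matrix with one-hot factor encoding
#'
#' Trees split numeric columns directly; factor and character columns are
#' expanded into one indicator column per level (no reference level is
#' dropped -- trees carry no intercept).  The returned schema allows the
#' same expansion to be replayed on new data: levels unseen at training
#' time map to all-zero indicators, a deterministic convention.
#'
#' @param df data.frame of covariates (numeric, logical, factor, character).
#' @return list with elements `X` (numeric matrix) and `schema`.
#' @keywords internal
build_design <- function(df) {
  stopifnot(is.data.frame(df))
  schema <- list(cols = names(df), levels = vector("list", ncol(df)))
  names(schema$levels) <- names(df)
  parts <- vector("list", ncol(df))
  for (j in seq_along(df)) {
    v <- df[[j]]
    nm <- names(df)[j]
    if (is.numeric(v) || is.logical(v)) {
      parts[[j]] <- matrix(as.numeric(v), ncol = 1,
                           dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      lv <- levels(f)
      schema$levels[[nm]] <- lv
      m <- matrix(0, nrow(df), length(lv),
                  dimnames = list(NULL, paste0(nm, "=", lv)))
      m[cbind(seq_len(nrow(df)), as.integer(f))] <- 1
      m[is.na(f), ] <- 0
      parts[[j]] <- m
    }
  }
  X <- do.call(cbind, parts)
  list(X = X, schema = schema)
}

#' @keywords internal
apply_design <- function(schema, df) {
  if (!all(schema$cols %in% names(df)))
    stop("newdata is missing columns: ",
         paste(setdiff(schema$cols, names(df)), collapse = ", "))
  parts <- vector("list", length(schema$cols))
  for (j in seq_along(schema$cols)) {
    nm <- schema$cols[j]
    v <- df[[nm]]
    lv <- schema$levels[[nm]]
    if (is.null(lv)) {
      if (!is.numeric(v) && !is.logical(v))
        stop("column ", nm, " was numeric at training time")
      parts[[j]] <- matrix(as.numeric(v), ncol = 1,
                           dimnames = list(NULL, nm))
    } else {
      f <- factor(as.character(v), levels = lv)
      m <- matrix(0, nrow(df), length(lv),
                  dimnames = list(NULL, paste0(nm, "=", lv)))
      idx <- !is.na(f)
      m[cbind(which(idx), as.integer(f)[idx])] <- 1
      parts[[j]] <- m
    }
  }
  do.call(cbind, parts)
}
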
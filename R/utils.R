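# internal helpers shared across modules

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' One global seed fans out to per-stage seeds by stable string hashing of
#' the stage name, so pipeline stages can be rerun independently yet
#' reproducibly.  The result is always in `[0, 2^31 - 2]`.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 48271) %% 2147483647)
}

# coerce cohort-like data to an integer code matrix (values 1..k per column)
# with attributes nlev (integer vector) and levels (list of label vectors)
as_discrete_matrix <- function(data) {
  if (is.matrix(data)) data <- as.data.frame(data)
  stopifnot(is.data.frame(data), ncol(data) >= 1L)
  p <- ncol(data)
  nlev <- integer(p)
  levs <- vector("list", p)
  xm <- matrix(0L, nrow(data), p, dimnames = list(NULL, names(data)))
  for (j in seq_len(p)) {
    col <- data[[j]]
    if (is.factor(col)) {
      levs[[j]] <- levels(col)
      xm[, j] <- as.integer(col)
    } else if (is.logical(col)) {
      levs[[j]] <- c("0", "1")
      xm[, j] <- as.integer(col) + 1L
    } else if (is.numeric(col) && all(col %in% c(0, 1))) {
      levs[[j]] <- c("0", "1")
      xm[, j] <- as.integer(col) + 1L
    } else {
      f <- factor(as.character(col))
      levs[[j]] <- levels(f)
      xm[, j] <- as.integer(f)
    }
    if (anyNA(xm[, j])) {
      stop("column '", names(data)[j], "' contains missing values")
    }
    nlev[j] <- length(levs[[j]])
  }
  names(levs) <- names(data)
  attr(xm, "nlev") <- stats::setNames(nlev, names(data))
  attr(xm, "levels") <- levs
  xm
}

# sum of c*log(c) over positive counts (0 log 0 := 0)
xlogx_sum <- function(cnt) {
  cnt <- cnt[cnt > 0]
  sum(cnt * log(cnt))
}
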
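#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## validation failure naming the offending dotted parameter path
abort_validation <- function(path, msg) {
  stop(sprintf("parameter validation failed at '%s': %s", path, msg),
       call. = FALSE)
}

check_prob <- function(x, path) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort_validation(path, "probability outside [0, 1]")
  }
  invisible(x)
}

check_nonneg <- function(x, path) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort_validation(path, "negative or non-finite value (cost/rate must be >= 0)")
  }
  invisible(x)
}

check_simplex <- function(x, path, tol = 1e-9) {
  check_prob(x, path)
  if (abs(sum(x) - 1) > tol) {
    abort_validation(path, sprintf("entries sum to %.12f, not 1", sum(x)))
  }
  invisible(x)
}

## discount factor for completed cycle k = 1..n: (1+r)^-k
discount_factors <- function(rate, n) (1 + rate)^-(seq_len(n))

## Long (age, sex, value) table -> lookup matrix rows = ages, cols = male/female
age_sex_matrix <- function(df, ages = NULL) {
  stopifnot(all(c("age", "sex", "value") %in% names(df)))
  ages <- ages %||% sort(unique(df$age))
  m <- matrix(NA_real_, nrow = length(ages), ncol = 2,
              dimnames = list(as.character(ages), c("male", "female")))
  for (sx in c("male", "female")) {
    sub <- df[df$sex == sx, ]
    m[as.character(sub$age), sx] <- sub$value
  }
  if (anyNA(m)) stop("age/sex table has missing cells", call. = FALSE)
  m
}

## value at (age, sex); ages clamped to the table range, step interpolation
## (value carried forward from the last tabulated age) for sparse tables
age_sex_lookup <- function(mat, age, sex) {
  ages <- as.numeric(rownames(mat))
  idx <- findInterval(pmin(pmax(age, min(ages)), max(ages)), ages)
  mat[cbind(idx, match(sex, colnames(mat)))]
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
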
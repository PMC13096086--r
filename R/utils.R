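# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("freqstate_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_invalid(msg)
  invisible(TRUE)
}

# Spatial (Pearson) correlation between topographies. Average-referenced maps
# have zero channel mean, so this reduces to the cosine of the two vectors.
spatial_cor <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# deterministic child seed, kept well below 2^31
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 69069 + o) %% 2147483629
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
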
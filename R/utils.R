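## Internal numerical helpers shared across model and generator code.

sigmoid <- function(x) 1 / (1 + exp(-x))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Softmax of a numeric vector, numerically stabilised.
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

## Row-wise softmax over the columns of a matrix.
rowSoftmax <- function(m) {
  z <- exp(m - apply(m, 1L, max))
  z / rowSums(z)
}

## Classed error so callers and tests can discriminate failure modes.
imvStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "imvLAI_error")))
}

assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    imvStop(sprintf("'%s' must be a single integer >= %d", name, min),
            "invalidArgumentError")
  }
  as.integer(x)
}

## Apply f(leaf_a, leaf_b) over two parameter trees with identical shape.
treeMap2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) treeMap2(x, y, f), a, b)
    return(out)
  }
  f(a, b)
}

treeApply <- function(a, f) {
  if (is.list(a)) return(lapply(a, treeApply, f))
  f(a)
}

treeZero <- function(a) treeApply(a, function(x) x * 0)

## Flatten a parameter tree to one numeric vector (used by tests and
## determinism checks; order is the recursive list order).
treeUnlist <- function(a) unlist(a, use.names = FALSE)
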
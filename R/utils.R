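# small shared helpers

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. All stochastic entry points route through this
# so a seed argument fully determines their output without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# branchless formulations (pmax/pmin are C-level, much faster than ifelse)
elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
elu_grad <- function(x) exp(pmin(x, 0))
lrelu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)
lrelu_grad <- function(x, slope = 0.2) slope + (1 - slope) * (x > 0)

# row-wise softmax of a matrix, -Inf entries allowed (masked out)
softmax_rows <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  E <- exp(M - mx)
  E / rowSums(E)
}

# `g` is the derivative from the pre-activation, `gout` (when the map is
# invertible enough) the cheaper derivative from the cached output:
# for ELU, y = exp(x) - 1 on the negative side, so dy/dx = min(y + 1, 1).
activation_fun <- function(name) {
  switch(name,
         elu = list(f = function(x) if (is.matrix(x)) cpp_elu(x) else elu(x),
                    g = elu_grad,
                    gout = function(y) {
                      if (is.matrix(y)) cpp_elu_gradout(y) else pmin(y + 1, 1)
                    }),
         relu = list(f = function(x) pmax(x, 0),
                     g = function(x) as.numeric(x > 0),
                     gout = function(y) as.numeric(y > 0)),
         identity = list(f = identity, g = function(x) rep(1, length(x)),
                         gout = function(y) rep(1, length(y))),
         tanh = list(f = tanh, g = function(x) 1 - tanh(x)^2,
                     gout = function(y) 1 - y^2),
         stop("unknown activation: ", name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
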
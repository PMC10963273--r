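# internal helpers

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopDomain <- function(...) stop(..., call. = FALSE)

checkSameShape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stopDomain(what, " have mismatching shapes: ",
               paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# Neighbourhood offset sets for 6/18/26 connectivity, rows = (dx, dy, dz).
connectivityOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  ord <- switch(as.character(connectivity),
                "6"  = rowSums(abs(g)) == 1L,
                "18" = rowSums(abs(g)) <= 2L,
                "26" = rep(TRUE, nrow(g)),
                stopDomain("connectivity must be 6, 18 or 26"))
  g[ord, , drop = FALSE]
}
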
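#' Derive a child seed from a master seed
#'
#' One master seed drives a whole multi-cohort simulation or permutation run;
#' every stage that needs its own RNG stream gets a child seed through this
#' fixed rule, so runs are reproducible and streams do not collide.
#'
#' The rule is `(master * 69069 + index * 1009 + stage) mod (2^31 - 2) + 1`,
#' evaluated in double precision (exact below 2^53).
#'
#' @param master Integer master seed.
#' @param index Integer index of the unit (cohort number, replicate number).
#' @param stage Integer stage offset distinguishing pipeline stages that share
#'   an index (default 0).
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' child_seed(42, 3)
child_seed <- function(master, index, stage = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2^31 - 2
  as.integer((abs(master) * 69069 + index * 1009 + stage) %% m + 1)
}

# stop with a classed condition so callers can test for specific failures
abort_survscan <- function(msg, class) {
  stop(structure(
    class = c(class, "survscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# inverse of a permutation vector: ip[p[i]] == i
inv_perm <- function(p) {
  ip <- integer(length(p))
  ip[p] <- seq_along(p)
  ip
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
}

z975 <- qnorm(0.975) # 1.959964...
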
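#' Collision-free child seeds
#'
#' Derives reproducible child seeds from a master seed: the master is mixed
#' through a 64-bit finaliser and each child index is mapped through an
#' affine step with an odd multiplier, reduced modulo 2^31. Because the
#' affine map is a bijection on the index space, distinct indices can never
#' produce the same child seed for a given master — replicate trajectories
#' and experiments each get a unique, independent-looking seed.
#'
#' @param master Integer master seed.
#' @param index Integer vector of child indices (>= 0; up to 2^31 distinct
#'   children are collision-free).
#' @return An integer vector of seeds in `[0, 2^31)`.
#' @examples
#' child_seeds(42, 1:5)
#' @export
child_seeds <- function(master, index) {
  stopifnot(length(master) == 1, is.finite(master), all(index >= 0))
  cpp_child_seeds(as.numeric(master), as.numeric(index))
}

# small FNV-1a over a string; used to fingerprint configs in run manifests
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h %% 2147483648, b) + (h %/% 2147483648) * 2147483648
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}
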
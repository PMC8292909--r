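# Shared numeric and RNG helpers.

# Uniform random rotation matrix (Shoemake's quaternion method). Draws three
# uniforms from the current RNG stream; caller controls seeding.
random_rotation <- function() {
  u <- runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  quat_to_matrix(q)
}

quat_to_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# 32-bit FNV-1a hash of a character string, returned as a double in
# [0, 2^32). Used for stable per-id sub-seeds and fingerprint hashing.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# XOR for doubles holding 32-bit unsigned values.
bitwXor32 <- function(a, b) {
  hi_a <- a %/% 2147483648; lo_a <- a %% 2147483648
  hi_b <- b %/% 2147483648; lo_b <- b %% 2147483648
  lo <- bitwXor(as.integer(lo_a), as.integer(lo_b))
  hi <- (hi_a + hi_b) %% 2
  hi * 2147483648 + as.double(lo)
}

# Combine a user seed with a stable per-id hash, keeping the result a valid
# 32-bit R integer. Makes per-compound randomness independent of table order.
sub_seed <- function(seed, id) {
  as.integer((as.double(seed) + fnv1a32(as.character(id))) %% 2147483647)
}

# Hash a sequence of non-negative integers (FNV-1a over their decimal forms,
# ";"-joined). Workhorse of the circular fingerprint.
hash_ints <- function(v) fnv1a32(paste(v, collapse = ";"))

# Pairwise min distance between two coordinate matrices (n x 3, m x 3).
min_cross_dist <- function(a, b) {
  sqrt(min(cross_dist2(a, b)))
}

# Squared distance matrix between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
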
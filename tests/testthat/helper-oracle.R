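# Brute-force folding oracle: exhaustive enumeration of pseudoknot-free
# structures with direct loop-decomposition scoring. Independent of the
# package's dynamic-programming engine; feasible for n <= ~14.

oracle_pair_type <- function(a, b) {
  key <- paste0(a, b)
  match(key, c("AU", "UA", "GC", "CG", "GU", "UG"))
}

oracle_params <- function(config = fold_config()) {
  c(config$parameters,
    list(min_hairpin = config$min_hairpin_loop, rt = config$rt))
}

# all structures on chars[i..j] as lists of c(i, j) pairs
oracle_enumerate <- function(chars, min_hairpin = 3L) {
  n <- length(chars)
  memo <- new.env()
  rec <- function(i, j) {
    if (j - i < min_hairpin + 1L) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i, j - 1L)                      # j unpaired
    for (k in i:(j - min_hairpin - 1L)) {      # j paired with k
      if (is.na(oracle_pair_type(chars[k], chars[j]))) next
      left <- if (k > i) rec(i, k - 1L) else list(list())
      inner <- rec(k + 1L, j - 1L)
      for (L in left) for (I in inner)
        out[[length(out) + 1L]] <- c(L, I, list(c(k, j)))
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# loop-decomposition energy of one structure; Inf when the structure falls
# outside the model (interior loop larger than max_interior)
oracle_energy <- function(pairs, chars, par) {
  if (length(pairs) == 0L) return(0)
  by_i <- pairs[order(vapply(pairs, `[`, 0, 1))]
  # children of the interval (i, j): pairs directly enclosed
  children_of <- function(i, j) {
    kids <- list()
    k <- i
    while (k <= j) {
      hit <- Filter(function(p) p[1] == k, by_i)
      if (length(hit)) {
        kids[[length(kids) + 1L]] <- hit[[1]]
        k <- hit[[1]][2] + 1L
      } else k <- k + 1L
    }
    kids
  }
  score_pair <- function(p) {
    i <- p[1]; j <- p[2]
    pt <- oracle_pair_type(chars[i], chars[j])
    kids <- children_of(i + 1L, j - 1L)
    if (length(kids) == 0L) {
      par$hairpin_a + par$hairpin_b * ((j - i - 1L) - par$min_hairpin)
    } else if (length(kids) == 1L) {
      k <- kids[[1]][1]; l <- kids[[1]][2]
      u <- (k - i - 1L) + (j - l - 1L)
      e <- if (u == 0L) {
        -(par$stack_half[pt] + par$stack_half[oracle_pair_type(chars[k],
                                                               chars[l])])
      } else if (u <= par$max_interior) {
        par$interior_a + par$interior_b * u
      } else Inf
      e + score_pair(kids[[1]])
    } else {
      unpaired <- (j - i - 1L) -
        sum(vapply(kids, function(q) q[2] - q[1] + 1L, 0L))
      par$ml_a + par$ml_b * (length(kids) + 1L) + par$ml_c * unpaired +
        sum(vapply(kids, score_pair, 0))
    }
  }
  sum(vapply(children_of(1L, length(chars)), score_pair, 0))
}

# full oracle: MFE, partition function, ensemble free energy, bppm
oracle_fold <- function(residues, config = fold_config()) {
  par <- oracle_params(config)
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  structs <- oracle_enumerate(chars, par$min_hairpin)
  energies <- vapply(structs, oracle_energy, 0, chars = chars, par = par)
  keep <- is.finite(energies)
  structs <- structs[keep]; energies <- energies[keep]
  w <- exp(-energies / par$rt)
  Z <- sum(w)
  bppm <- matrix(0, n, n)
  for (s in seq_along(structs)) for (p in structs[[s]]) {
    bppm[p[1], p[2]] <- bppm[p[1], p[2]] + w[s]
    bppm[p[2], p[1]] <- bppm[p[2], p[1]] + w[s]
  }
  list(e_mfe = min(energies), Z = Z, g_ensemble = -par$rt * log(Z),
       bppm = bppm / Z)
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# independent adjacent-pair tally (for shuffle conservation checks)
oracle_dinuc_table <- function(res) {
  chars <- strsplit(res, "")[[1]]
  if (length(chars) < 2) return(table(character()))
  table(paste0(chars[-length(chars)], chars[-1]))
}
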
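# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity from first principles with
# scalar code, sharing nothing with the package internals.

# --- Weir-Cockerham (1984) theta, per-locus scalar evaluation -------------
oracle_wc_theta <- function(geno_list) {
  # geno_list: one genotype vector (0/1/2, NA allowed) per population,
  # loci in columns of a matrix per population
  n_loci <- ncol(geno_list[[1]])
  A <- B <- C <- 0
  for (l in seq_len(n_loci)) {
    ns <- ps <- hs <- numeric(0)
    for (pop in geno_list) {
      g <- pop[, l]
      g <- g[!is.na(g)]
      if (length(g) == 0) next
      ns <- c(ns, length(g))
      ps <- c(ps, sum(g) / (2 * length(g)))
      hs <- c(hs, mean(g == 1))
    }
    r <- length(ns)
    if (r < 2) next
    if (sum(ps * ns) == 0 || sum(ps * ns) == sum(ns)) next  # monomorphic
    nbar <- mean(ns)
    nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
    pbar <- sum(ns * ps) / sum(ns)
    s2 <- sum(ns * (ps - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * hs) / sum(ns)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

# --- HWE exact test by direct enumeration --------------------------------
oracle_hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n - na
  rare <- min(na, nb)
  if (rare == 0 || n < 2) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- sapply(hets, function(h) {
    naa <- (rare - h) / 2
    nbb <- n - naa - h
    if (nbb < 0) return(0)
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
          h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
          lfactorial(2 * n))
  })
  prob <- prob / sum(prob)
  obs <- prob[hets == n_ab]
  sum(prob[prob <= obs + 1e-12])
}

# --- betweenness by exhaustive shortest-path enumeration -----------------
oracle_betweenness <- function(n_nodes, edges) {
  # edges: 2-column matrix of node indices; unweighted undirected graph
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  # all simple paths between s and t, keep the shortest ones
  all_paths <- function(s, t) {
    paths <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        paths[[length(paths) + 1]] <<- path
        return()
      }
      for (nb in adj[[last]]) {
        if (!(nb %in% path)) grow(c(path, nb))
      }
    }
    grow(s)
    paths
  }
  btw <- numeric(n_nodes)
  for (s in seq_len(n_nodes - 1)) {
    for (t in seq(s + 1, n_nodes)) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- sapply(paths, length)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(shortest)
      }
    }
  }
  btw
}

# --- Delaunay triangle set via empty-circumcircle definition -------------
oracle_delaunay_edges <- function(x, y) {
  n <- length(x)
  edges <- matrix(integer(0), ncol = 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ux - ax)^2 + (uy - ay)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (x[others] - ux)^2 + (y[others] - uy)^2
    if (all(d2 > r2 * (1 + 1e-9))) {
      edges <- rbind(edges, c(i, j), c(j, k), c(i, k))
    }
  }
  unique(t(apply(edges, 1, sort)))
}

# --- three-level AMOVA from pairwise squared distances -------------------
oracle_amova <- function(X, site, group) {
  # X: individuals x markers (complete); distance formulation of the sums
  # of squares: SS of a set = sum of pairwise squared distances / set size
  d2 <- as.matrix(dist(X))^2
  ss_of <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  N <- nrow(X)
  ss_total <- ss_of(seq_len(N))
  sites <- unique(site)
  groups <- unique(group)
  ss_within_sites <- sum(sapply(sites, function(s) ss_of(which(site == s))))
  ss_within_groups <- sum(sapply(groups, function(g) ss_of(which(group == g))))
  ss_among_sites <- ss_within_groups - ss_within_sites
  ss_among_groups <- ss_total - ss_within_groups

  S <- length(sites); G <- length(groups)
  n_s <- sapply(sites, function(s) sum(site == s))
  grp_of_site <- sapply(sites, function(s) group[which(site == s)[1]])
  N_g <- sapply(groups, function(g) sum(group == g))

  df_ag <- G - 1; df_as <- S - G; df_ws <- N - S
  ms_ws <- if (df_ws > 0) ss_within_sites / df_ws else 0
  sum_ns2_by_g <- sapply(groups, function(g)
    sum(n_s[grp_of_site == g]^2))
  n_in_g <- sapply(groups, function(g) sum(n_s[grp_of_site == g]))
  n1 <- if (df_as > 0) (N - sum(sum_ns2_by_g / n_in_g)) / df_as else NA
  n2 <- (sum(sum_ns2_by_g / n_in_g) - sum(n_s^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag
  sigma_c <- ms_ws
  sigma_b <- if (df_as > 0 && is.finite(n1) && n1 > 0)
    (ss_among_sites / df_as - sigma_c) / n1 else 0
  sigma_a <- (ss_among_groups / df_ag - sigma_c - n2 * sigma_b) / n3
  list(ss = c(ss_among_groups, ss_among_sites, ss_within_sites),
       variance = c(sigma_a, sigma_b, sigma_c),
       ss_total = ss_total)
}

# --- partial RDA by centre / residualise / SVD ---------------------------
oracle_rda_eig <- function(Y, X, Z = NULL) {
  Y <- scale(as.matrix(Y), scale = FALSE)
  X <- scale(as.matrix(X), scale = FALSE)
  if (!is.null(Z)) {
    Z <- scale(as.matrix(Z), scale = FALSE)
    Y <- resid(lm.fit(Z, Y))
    X <- resid(lm.fit(Z, X))
  }
  fitted <- X %*% solve(crossprod(X), crossprod(X, Y))
  sv <- svd(fitted)
  eig <- sv$d^2 / (nrow(Y) - 1)
  eig[eig > 1e-10]
}
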
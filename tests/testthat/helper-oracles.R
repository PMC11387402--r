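# Independent oracles used across the suite. These deliberately avoid the
# package's own formula/statistics code paths: compositions are built by
# plain named-vector arithmetic from building blocks, masses are summed by
# hand from an independent constant table, and test statistics are
# evaluated from their textbook formulas or by enumeration.

# --- composition oracle: backbone + headgroup + fatty acyls - water ----

o_counts <- function(...) {
  x <- c(...)
  x[x != 0]
}

o_add <- function(a, b, times = 1) {
  syms <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(syms)), syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + times * b
  out[out != 0]
}

# total fatty-acyl block over `chains` chains with n carbons, d double
# bonds in sum composition: each chain contributes CnH(2n-2d)O2
o_fatty_acid <- function(n, d, chains = 1) {
  o_counts(C = n, H = 2 * n - 2 * d, O = 2 * chains)
}
o_water <- o_counts(H = 2, O = 1)
o_glycerol <- o_counts(C = 3, H = 8, O = 3)
o_phosphate <- o_counts(H = 3, O = 4, P = 1)

# glycerophospholipid: glycerol + phosphate + headgroup + n_chains FA,
# minus one water per condensation
o_gpl <- function(head, n_chains, n, d, extra_condensations = 2) {
  x <- o_add(o_glycerol, o_phosphate)
  x <- o_add(x, head)
  x <- o_add(x, o_fatty_acid(n, d, chains = n_chains))
  x <- o_add(x, o_water, times = -(n_chains + extra_condensations))
  x
}

o_heads <- list(
  none = o_counts(),
  choline = o_counts(C = 5, H = 13, N = 1, O = 1),
  ethanolamine = o_counts(C = 2, H = 7, N = 1, O = 1),
  glycerol = o_glycerol,
  inositol = o_counts(C = 6, H = 12, O = 6),
  serine = o_counts(C = 3, H = 7, N = 1, O = 3)
)

# sum-composition formula oracle per class (counts, not strings)
oracle_composition <- function(class_code, n, d) {
  switch(
    class_code,
    LPC = o_gpl(o_heads$choline, 1, n, d),
    PC = o_gpl(o_heads$choline, 2, n, d),
    LPE = o_gpl(o_heads$ethanolamine, 1, n, d),
    PE = o_gpl(o_heads$ethanolamine, 2, n, d),
    LPG = o_gpl(o_heads$glycerol, 1, n, d),
    PG = o_gpl(o_heads$glycerol, 2, n, d),
    LPA = o_gpl(o_heads$none, 1, n, d, extra_condensations = 1),
    PA = o_gpl(o_heads$none, 2, n, d, extra_condensations = 1),
    PI = o_gpl(o_heads$inositol, 2, n, d),
    PS = o_gpl(o_heads$serine, 2, n, d),
    DG = o_add(o_add(o_glycerol, o_fatty_acid(n, d, 2)), o_water, -2),
    TG = o_add(o_add(o_glycerol, o_fatty_acid(n, d, 3)), o_water, -3),
    CE = o_add(o_add(o_counts(C = 27, H = 46, O = 1),
                     o_fatty_acid(n, d)), o_water, -1),
    # ceramide: d-type sphingoid (2 OH) + amide-linked FA; d includes the
    # sphingoid ene. Built from sphinganine C18H39NO2 generalized to
    # chain total n, unsaturation d.
    Cer = o_counts(C = n, H = 2 * n + 1 - 2 * d, N = 1, O = 3),
    SM = o_add(o_add(o_counts(C = n, H = 2 * n + 1 - 2 * d, N = 1, O = 3),
                     o_counts(C = 5, H = 14, N = 1, O = 4, P = 1)),
               o_water, -1),
    CL = {
      x <- o_add(o_glycerol, o_glycerol)
      x <- o_add(x, o_glycerol)
      x <- o_add(x, o_phosphate, 2)
      x <- o_add(x, o_fatty_acid(n, d, 4))
      o_add(x, o_water, -8)
    },
    stop("no oracle for class ", class_code)
  )
}

# --- mass oracle: independent constants, plain weighted sum -----------

o_masses <- c(C = 12, H = 1.00782503, D = 2.01410178, N = 14.00307401,
              O = 15.99491462, P = 30.97376163, Na = 22.98976928)
o_proton <- 1.00727647

oracle_mass <- function(counts) sum(o_masses[names(counts)] * counts)

# --- statistics oracles ----------------------------------------------

# exact two-sided Mann-Whitney p by enumeration of all assignments
oracle_mwu_exact_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    ga <- pooled[idx]
    gb <- pooled[-idx]
    sum(outer(ga, gb, ">")) + 0.5 * sum(outer(ga, gb, "=="))
  }
  obs <- u_of(seq_len(na))
  all_u <- apply(utils::combn(length(pooled), na), 2, u_of)
  mu <- na * (length(pooled) - na) / 2
  mean(abs(all_u - mu) >= abs(obs - mu) - 1e-12)
}

# Welch statistic/df/p straight from the formulas
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Spearman rho via midranks and the product-moment formula, by hand
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# tie-corrected Kruskal-Wallis statistic from rank arithmetic
oracle_kw_stat <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# linear-scan catalog query oracle
oracle_query <- function(catalog, mz, tol_ppm, polarity = NULL) {
  ppm <- (mz - catalog$mz) / catalog$mz * 1e6
  keep <- abs(ppm) <= tol_ppm
  if (!is.null(polarity)) keep <- keep & catalog$polarity == polarity
  out <- catalog[keep, ]
  out$ppm_error <- ppm[keep]
  tibble::as_tibble(out)
}

# small toy template builder for catalog tests
toy_template <- function(class_code = "LPC", carbon = c(24, 26),
                         db = c(0, 0), adducts = c("[M+H]+", "[M+Na]+")) {
  tpl <- lipid_class_templates()
  tpl <- tpl[tpl$class_code == class_code, ]
  tpl$carbon_min <- min(carbon)
  tpl$carbon_max <- max(carbon)
  tpl$db_min <- min(db)
  tpl$db_max <- max(db)
  tpl$adducts <- list(adducts)
  tpl
}
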
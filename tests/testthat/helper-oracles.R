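# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's own code paths (and igraph) so the
# tests compare two independent routes to the same quantity.

make_peptides <- function(peptide_id, protein_id, intensity,
                          sex = "M", group = "CT", pool = 1L, tech = 1L) {
  tibble::tibble(
    peptide_id = peptide_id, protein_id = protein_id,
    sex = sex, group = group, pool = as.integer(pool),
    tech = as.integer(tech), intensity = intensity
  )
}

# Random long-format peptide table over n_proteins, with per-protein
# random peptide counts and random presence across runs.
random_peptides <- function(n_proteins = 50, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_proteins)) {
    prot <- sprintf("P%04d", i)
    n_pep <- sample(1:6, 1)
    for (j in seq_len(n_pep)) {
      runs <- expand.grid(sex = "M", group = c("CT", "PCP"),
                          pool = 1:4, tech = 1:3,
                          stringsAsFactors = FALSE)
      keep <- runif(nrow(runs)) < runif(1, 0.2, 1)
      if (!any(keep)) next
      runs <- runs[keep, ]
      rows[[length(rows) + 1]] <- tibble::tibble(
        peptide_id = sprintf("%s.p%d", prot, j), protein_id = prot,
        sex = runs$sex, group = runs$group,
        pool = as.integer(runs$pool), tech = as.integer(runs$tech),
        intensity = rlnorm(nrow(runs), log(1e5), 1)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Brute-force identification filter: explicit per-protein scan.
oracle_filter <- function(peptides, min_peptides = 2, min_runs = 2) {
  keep <- character(0)
  for (prot in unique(peptides$protein_id)) {
    sub <- peptides[peptides$protein_id == prot, ]
    n_pep <- length(unique(sub$peptide_id))
    n_run <- nrow(unique(sub[, c("sex", "group", "pool", "tech")]))
    if (n_pep >= min_peptides && n_run >= min_runs) keep <- c(keep, prot)
  }
  sort(keep)
}

# Brute-force Hi3: sort each cell's intensities, average the top 3.
oracle_hi3 <- function(peptides) {
  cells <- unique(peptides[, c("protein_id", "sex", "group", "pool",
                               "tech")])
  cells$abundance <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- peptides$protein_id == cells$protein_id[i] &
      peptides$sex == cells$sex[i] & peptides$group == cells$group[i] &
      peptides$pool == cells$pool[i] & peptides$tech == cells$tech[i]
    x <- sort(peptides$intensity[sel], decreasing = TRUE)
    cells$abundance[i] <- mean(x[seq_len(min(3, length(x)))])
  }
  cells
}

# Brute-force Venn partition: test every membership signature.
oracle_venn <- function(family) {
  nms <- names(family)
  universe <- unique(unlist(family))
  out <- list()
  for (size in seq_along(nms)) {
    for (j in seq_len(ncol(utils::combn(nms, size)))) {
      inside <- utils::combn(nms, size)[, j]
      outside <- setdiff(nms, inside)
      region <- universe
      for (nm in inside) region <- intersect(region, family[[nm]])
      for (nm in outside) region <- setdiff(region, family[[nm]])
      if (length(region) > 0) {
        out[[paste(inside, collapse = "&")]] <- region
      }
    }
  }
  out
}

# Brute-force betweenness by exhaustive simple-path enumeration: for
# every unordered pair, list all simple paths, keep the shortest, and
# credit interior vertices with the fraction passing through them.
oracle_betweenness <- function(edges_df, vertices) {
  adj <- lapply(setNames(vertices, vertices), function(v) {
    c(edges_df$protein_b[edges_df$protein_a == v],
      edges_df$protein_a[edges_df$protein_b == v])
  })
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(visited))
    out <- list()
    for (nb in setdiff(adj[[from]], visited)) {
      out <- c(out, all_paths(nb, to, c(visited, nb)))
    }
    out
  }
  btw <- setNames(rep(0, length(vertices)), vertices)
  pairs <- utils::combn(vertices, 2)
  for (k in seq_len(ncol(pairs))) {
    paths <- all_paths(pairs[1, k], pairs[2, k], pairs[1, k])
    if (length(paths) == 0) next
    len <- vapply(paths, length, integer(1))
    shortest <- paths[len == min(len)]
    for (p in shortest) {
      interior <- setdiff(p, c(pairs[1, k], pairs[2, k]))
      btw[interior] <- btw[interior] + 1 / length(shortest)
    }
  }
  btw
}

# Random undirected graph as an edge tibble, guaranteed simple.
random_edges <- function(n_nodes, p, seed, confidence = 0.9) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- utils::combn(ids, 2)
  keep <- runif(ncol(pairs)) < p
  tibble::tibble(protein_a = pairs[1, keep], protein_b = pairs[2, keep],
                 confidence = confidence)
}

# Pool-level abundance table with explicit values for one protein.
pool_rows <- function(values_by_group, sex = "M",
                      protein_id = "P0001") {
  dplyr::bind_rows(lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    tibble::tibble(protein_id = protein_id, sex = sex, group = g,
                   pool = seq_along(v), abundance = v,
                   n_tech_used = 3L, level = "pool")
  }))
}

# The six-comparison lattice from explicitly given DE protein sets:
# builds minimal lfq_comparison objects for set-algebra tests. Each DE
# protein gets direction "up" unless listed in `down`.
fake_comparison <- function(focal, reference, de, sex = "M",
                            down = character(0)) {
  all_ids <- unique(de)
  records <- tibble::tibble(
    protein_id = all_ids,
    n_present_focal = 4L, n_present_ref = 4L,
    mean_focal = ifelse(all_ids %in% down, 1, 2),
    mean_ref = 1.5,
    cv_focal = 0.1, cv_ref = 0.1, fold_change = 2,
    f_stat = 50, p_value = 0.001, q_value = 0.001,
    direction = ifelse(all_ids %in% down, "down", "up"),
    stats_defined = TRUE,
    pass_presence = TRUE, pass_cv = TRUE, pass_fc = TRUE,
    pass_anova = TRUE, filter_failed = NA_character_, is_de = TRUE
  )
  structure(list(sex = sex, focal = focal, reference = reference,
                 thresholds = de_thresholds(), records = records),
            class = "lfq_comparison")
}

# All six comparisons of the default lattice from a named list of DE
# sets keyed like "PCPNIC vs CT".
fake_lattice_results <- function(de_sets, sex = "M",
                                 down = character(0)) {
  lat <- comparison_lattice(c("CT", "PCP", "NIC", "PCPNIC"))
  lapply(seq_len(nrow(lat)), function(i) {
    fake_comparison(lat$focal[i], lat$reference[i],
                    de_sets[[lat$name[i]]] %||% character(0),
                    sex = sex, down = down)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
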
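# Synthetic study generator: a proteome with planted domain-bearing family
# members and decoys, a genome annotation with planted clusters and
# duplicate pairs, a second species for orthology, negative-binomial tissue
# counts and qPCR Ct tables -- all from one seed, with a ground-truth
# manifest that records every planted fact.

#' Generator configuration
#'
#' Defaults describe a willow-scale family census: class sizes 11/7/4/32/6
#' (M-type classes carry 0-1 introns, MIKC-type classes 4-13 introns plus a
#' K-like domain), 60 background decoys, duplicate pairs at 80 percent
#' identity placed tandem (same chromosome, adjacent) or segmental
#' (different chromosomes), gene clusters within 200-kb start-to-start
#' spacing, a second species holding orthologs at 90 percent identity, and
#' five-tissue negative-binomial counts with a planted root depletion.
#'
#' @param seed Integer master seed; every stream derives from it.
#' @param ... Named overrides of any default listed in the function body.
#' @return List of class \code{"generator_config"}.
#' @export
generator_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_per_class = setNames(c(11L, 7L, 4L, 32L, 6L), family_classes()),
    n_decoys = 60L,
    n_truncated = 2L,
    n_chromosomes = 10L,
    chromosome_length = 6e6,
    domain_width = 60L,
    k_width = 92L,
    n_seed_rows = 8L,
    seed_mutation = 0.10,
    class_divergence = 0.08,
    member_divergence = 0.02,
    n_tandem_dups = 2L,
    n_segmental_dups = 3L,
    dup_identity = 0.80,
    cluster_sizes = c(2L, 3L, 2L),
    within_cluster_gap = c(6e4, 1.5e5),
    between_unit_gap = c(3e5, 4e5),
    ortholog_fraction = 0.5,
    ortholog_identity = 0.90,
    n_b_decoys = 20L,
    intron_range_m = c(0L, 1L),
    intron_range_mikc = c(4L, 13L),
    intron_length_range = c(100L, 1000L),
    flank_n_range = c(10L, 30L),
    linker_range = c(25L, 35L),
    flank_c_range = c(350L, 450L),
    zipper_fraction = 1 / 3,
    tissues = c("root", "stem", "leaf", "bud", "bark"),
    root_multiplier = 0.4,
    other_multiplier_range = c(0.8, 1.4),
    nb_dispersion = 5,
    base_meanlog = 4,
    base_sdlog = 1,
    lib_size_range = c(1.8e6, 2.4e6),
    n_qpcr_genes = 6L,
    ct_base_range = c(20, 30),
    ct_noise_sd = 0.1,
    reference_gene = "OTU",
    calibrator_tissue = "root"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (any(unlist(cfg$n_per_class) < 0) || cfg$n_decoys < 0) stop("counts must be >= 0")
  if (cfg$dup_identity <= 0 || cfg$dup_identity >= 1) stop("identities must be in (0,1)")
  structure(cfg, class = "generator_config")
}

# fixed offsets per random stream: adding a stream never perturbs the others
stream_seed <- function(seed, offset) {
  set.seed((abs(seed) %% 100000L) * 10000L + offset)
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# substitute a fraction of positions with a different residue
mutate_fraction <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  k <- round(rate * length(chars))
  if (k == 0) return(seq)
  pos <- sample(length(chars), k)
  chars[pos] <- vapply(chars[pos], function(a) sample(setdiff(AA20, a), 1), "")
  paste(chars, collapse = "")
}

# mutate outside protected positions until the global-alignment identity to
# the original hits the target; equal-length substitution-only copies make
# identity = 1 - k/L exact
mutate_to_identity <- function(seq, target, protect = integer(0)) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  k <- round((1 - target) * L)
  free <- setdiff(seq_len(L), protect)
  if (k > length(free)) {
    stop("cannot reach identity ", target, ": too few unprotected positions")
  }
  pos <- sample(free, k)
  chars[pos] <- vapply(chars[pos], function(a) sample(setdiff(AA20, a), 1), "")
  paste(chars, collapse = "")
}

#' Generate a synthetic study with ground truth
#'
#' Emits a proteome (family members with planted domains at recorded
#' offsets, background decoys, truncated-domain decoys), a GFF3 genome
#' annotation with planted tandem/segmental duplicate pairs and gene
#' clusters, seed alignments for the core and K domains, class-centroid
#' reference proteins with labels, a second-species proteome with planted
#' ortholog pairs, five-tissue negative-binomial read counts with a planted
#' root depletion, and a qPCR Ct table built as
#' \code{ct_base - log2(multiplier) + noise}. All randomness derives from
#' \code{config$seed} through fixed per-stream offsets, so identical
#' configurations regenerate byte-identical files.
#'
#' @param config A \code{\link{generator_config}}.
#' @param outdir Output directory for the emitted files, or \code{NULL} to
#'   generate in memory only.
#' @return List with \code{config}, \code{proteins}, \code{species_b},
#'   \code{gene_models}, \code{refs}, \code{ref_labels}, \code{seed_mads},
#'   \code{seed_k}, \code{counts} (a \code{\link{count_matrix}}), \code{ct},
#'   \code{manifest}, and \code{paths} when files were written.
#' @export
generate_family_data <- function(config = generator_config(), outdir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config

  ## stream 101: seed alignments for the two domains
  stream_seed(cfg$seed, 101L)
  consensus_mads <- random_protein(cfg$domain_width)
  consensus_k <- random_protein(cfg$k_width)
  seed_mads <- seed_alignment(
    ids = sprintf("seed%02d", seq_len(cfg$n_seed_rows)),
    aligned = vapply(seq_len(cfg$n_seed_rows), function(i)
      mutate_fraction(consensus_mads, cfg$seed_mutation), "")
  )
  seed_k <- seed_alignment(
    ids = sprintf("kseed%02d", seq_len(cfg$n_seed_rows)),
    aligned = vapply(seq_len(cfg$n_seed_rows), function(i)
      mutate_fraction(consensus_k, cfg$seed_mutation), "")
  )

  ## stream 211: members, references, decoys, duplicates
  stream_seed(cfg$seed, 211L)
  classes <- rep(names(cfg$n_per_class), unlist(cfg$n_per_class))
  n_members <- length(classes)
  centroid_mads <- lapply(setNames(nm = names(cfg$n_per_class)), function(cl)
    mutate_fraction(consensus_mads, cfg$class_divergence))
  centroid_k <- lapply(setNames(nm = mikc_type_classes()), function(cl)
    mutate_fraction(consensus_k, cfg$class_divergence))

  member_ids <- sprintf("M%03d", seq_len(n_members))
  proteins <- character(0)
  domain_offset <- integer(n_members)
  k_offset <- rep(NA_integer_, n_members)
  has_zipper <- logical(n_members)
  rint <- function(range) if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)
  for (i in seq_len(n_members)) {
    cl <- classes[i]
    dom <- mutate_fraction(centroid_mads[[cl]], cfg$member_divergence)
    nflank <- random_protein(rint(cfg$flank_n_range))
    if (cl %in% mikc_type_classes()) {
      linker <- random_protein(rint(cfg$linker_range))
      kdom <- mutate_fraction(centroid_k[[cl]], cfg$member_divergence)
      zip <- ""
      if (runif(1) < cfg$zipper_fraction) {
        basic <- paste(sample(c("K", "R"), 10, replace = TRUE), collapse = "")
        heptads <- paste(vapply(1:4, function(r)
          paste0("L", paste(sample(setdiff(AA20, "L"), 6, replace = TRUE),
                            collapse = "")), ""), collapse = "")
        zip <- paste0(basic, heptads)
        has_zipper[i] <- TRUE
      }
      cflank <- random_protein(rint(cfg$flank_c_range))
      seq <- paste0(nflank, dom, linker, kdom, zip, cflank)
      k_offset[i] <- nchar(nflank) + nchar(dom) + nchar(linker) + 1L
    } else {
      cflank <- random_protein(rint(cfg$flank_c_range))
      seq <- paste0(nflank, dom, cflank)
    }
    domain_offset[i] <- nchar(nflank) + 1L
    proteins[member_ids[i]] <- seq
  }

  # duplicate pairs: partner rebuilt as a mutated copy of its mate, domain
  # and K regions protected so the partner stays identifiable
  n_dups <- cfg$n_tandem_dups + cfg$n_segmental_dups
  mikcc_idx <- which(classes == "MIKCc")
  if (2 * n_dups > length(mikcc_idx)) stop("not enough MIKCc members for duplicate pairs")
  dup_slots <- matrix(sample(mikcc_idx, 2 * n_dups), ncol = 2)
  dup_pairs <- data.frame(id_a = character(0), id_b = character(0),
                          category = character(0), target_identity = numeric(0),
                          realized_identity = numeric(0), stringsAsFactors = FALSE)
  for (d in seq_len(n_dups)) {
    a <- dup_slots[d, 1]; b <- dup_slots[d, 2]
    src <- proteins[[member_ids[a]]]
    protect <- c(seq(domain_offset[a], domain_offset[a] + cfg$domain_width - 1),
                 if (!is.na(k_offset[a])) seq(k_offset[a], k_offset[a] + cfg$k_width - 1))
    copy <- mutate_to_identity(src, cfg$dup_identity, protect = protect)
    proteins[member_ids[b]] <- copy
    domain_offset[b] <- domain_offset[a]
    k_offset[b] <- k_offset[a]
    has_zipper[b] <- FALSE
    realized <- 1 - global_identity_distance(src, copy)  # equal length, no gaps
    dup_pairs <- rbind(dup_pairs, data.frame(
      id_a = member_ids[a], id_b = member_ids[b],
      category = if (d <= cfg$n_tandem_dups) "tandem" else "segmental",
      target_identity = cfg$dup_identity, realized_identity = realized,
      stringsAsFactors = FALSE))
  }

  # identification + classification references: the class centroids (bare
  # core domain for M-type, domain + K for MIKC-type)
  refs <- vapply(names(cfg$n_per_class), function(cl) {
    if (cl %in% mikc_type_classes()) {
      paste0(centroid_mads[[cl]], centroid_k[[cl]])
    } else {
      centroid_mads[[cl]]
    }
  }, "")
  names(refs) <- sprintf("REF%d", seq_along(refs))
  ref_labels <- setNames(names(cfg$n_per_class), names(refs))

  decoy_ids <- sprintf("D%03d", seq_len(cfg$n_decoys))
  for (id in decoy_ids) proteins[id] <- random_protein(rint(c(150L, 400L)))
  trunc_ids <- if (cfg$n_truncated > 0) sprintf("T%02d", seq_len(cfg$n_truncated)) else character(0)
  for (id in trunc_ids) {
    half <- substr(consensus_mads, 1, floor(cfg$domain_width / 2))
    proteins[id] <- paste0(random_protein(rint(cfg$flank_n_range)), half,
                           random_protein(rint(cfg$flank_c_range)))
  }
  validate_protein_set(proteins)

  ## stream 307: gene structures and chromosomal placement
  stream_seed(cfg$seed, 307L)
  all_ids <- c(member_ids, decoy_ids, trunc_ids)
  introns <- setNames(integer(length(all_ids)), all_ids)
  for (i in seq_len(n_members)) {
    rng <- if (classes[i] %in% m_type_classes()) cfg$intron_range_m else cfg$intron_range_mikc
    introns[member_ids[i]] <- rint(rng)
  }
  for (d in dup_pairs$id_b) introns[d] <- introns[dup_pairs$id_a[dup_pairs$id_b == d]]
  for (id in c(decoy_ids, trunc_ids)) introns[id] <- rint(c(0L, 8L))

  # placement units
  dup_a <- dup_pairs$id_a; dup_b <- dup_pairs$id_b
  tandem_units <- lapply(seq_len(cfg$n_tandem_dups), function(d)
    c(dup_a[d], dup_b[d]))
  seg_pairs <- lapply(seq_len(cfg$n_segmental_dups), function(d)
    c(dup_a[cfg$n_tandem_dups + d], dup_b[cfg$n_tandem_dups + d]))
  used <- c(unlist(tandem_units), unlist(seg_pairs))
  free_members <- setdiff(member_ids, used)
  cluster_units <- list()
  for (sz in cfg$cluster_sizes) {
    if (length(free_members) < sz) stop("not enough free members for clusters")
    cluster_units[[length(cluster_units) + 1]] <- free_members[seq_len(sz)]
    free_members <- free_members[-seq_len(sz)]
  }
  singles <- as.list(c(free_members, unlist(seg_pairs), decoy_ids, trunc_ids))
  # segmental mates must land on different chromosomes: pin them first
  seg_chrom <- list()
  for (d in seq_along(seg_pairs)) {
    c1 <- ((2 * d - 2) %% cfg$n_chromosomes) + 1
    c2 <- ((2 * d - 1) %% cfg$n_chromosomes) + 1
    if (c1 == c2) c2 <- (c2 %% cfg$n_chromosomes) + 1
    seg_chrom[[seg_pairs[[d]][1]]] <- c1
    seg_chrom[[seg_pairs[[d]][2]]] <- c2
  }
  units <- c(tandem_units, cluster_units, singles)
  chrom_names <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  cursor <- setNames(round(runif(cfg$n_chromosomes, 1e4, 5e4)), chrom_names)
  rr <- 0L
  gene_models <- list()
  make_structure <- function(id) {
    cds <- 3 * nchar(proteins[[id]]) + 3
    n_ex <- introns[[id]] + 1L
    if (n_ex == 1) {
      ex_len <- cds
    } else {
      w <- runif(n_ex)
      ex_len <- 3 + floor((cds - 3 * n_ex) * w / sum(w))
      ex_len[1] <- ex_len[1] + (cds - sum(ex_len))
    }
    int_len <- if (n_ex > 1) sample(cfg$intron_length_range[1]:cfg$intron_length_range[2],
                                    n_ex - 1, replace = TRUE) else integer(0)
    list(ex_len = ex_len, int_len = int_len,
         span = sum(ex_len) + sum(int_len))
  }
  place_gene <- function(id, chr, at) {
    st <- make_structure(id)
    ex_start <- at + cumsum(c(0, st$ex_len[-length(st$ex_len)] + st$int_len))
    ex_end <- ex_start + st$ex_len - 1
    gene_models[[id]] <<- gene_model(
      gene_id = id, chromosome = chr, start = at, end = max(ex_end),
      strand = sample(c("+", "-"), 1), exons = cbind(ex_start, ex_end))
    max(ex_end)
  }
  planted_clusters <- list()
  for (u in units) {
    first <- u[1]
    if (!is.null(seg_chrom[[first]])) {
      chr_idx <- seg_chrom[[first]]
    } else {
      rr <- (rr %% cfg$n_chromosomes) + 1L
      chr_idx <- rr
    }
    chr <- chrom_names[chr_idx]
    at <- cursor[[chr]]
    last_end <- at
    starts <- numeric(length(u))
    for (k in seq_along(u)) {
      starts[k] <- at
      last_end <- place_gene(u[k], chr, at)
      if (k < length(u)) at <- at + round(runif(1, cfg$within_cluster_gap[1],
                                                cfg$within_cluster_gap[2]))
    }
    cursor[[chr]] <- last_end + round(runif(1, cfg$between_unit_gap[1],
                                            cfg$between_unit_gap[2]))
    if (cursor[[chr]] > cfg$chromosome_length) {
      stop("infeasible placement: chromosome ", chr, " exceeded; increase ",
           "chromosome_length or n_chromosomes")
    }
    if (length(u) >= 2 && all(u %in% member_ids)) {
      planted_clusters[[length(planted_clusters) + 1]] <-
        list(chromosome = chr, members = u)
    }
  }
  gene_models <- gene_models[all_ids]
  for (p in seq_len(nrow(dup_pairs))) {
    ca <- gene_models[[dup_pairs$id_a[p]]]$chromosome
    cb <- gene_models[[dup_pairs$id_b[p]]]$chromosome
    expected <- dup_pairs$category[p]
    stopifnot((expected == "tandem") == (ca == cb))
  }

  ## stream 401: second species
  stream_seed(cfg$seed, 401L)
  n_orth <- round(cfg$ortholog_fraction * n_members)
  orth_members <- sort(sample(member_ids, n_orth))
  species_b <- character(0)
  ortholog_pairs <- data.frame(id_a = character(0), id_b = character(0),
                               stringsAsFactors = FALSE)
  for (m in orth_members) {
    i <- match(m, member_ids)
    protect <- c(seq(domain_offset[i], domain_offset[i] + cfg$domain_width - 1),
                 if (!is.na(k_offset[i])) seq(k_offset[i], k_offset[i] + cfg$k_width - 1))
    bid <- paste0("B_", m)
    species_b[bid] <- mutate_to_identity(proteins[[m]], cfg$ortholog_identity,
                                         protect = protect)
    ortholog_pairs <- rbind(ortholog_pairs,
                            data.frame(id_a = m, id_b = bid, stringsAsFactors = FALSE))
  }
  for (k in seq_len(cfg$n_b_decoys)) {
    species_b[sprintf("B_D%03d", k)] <- random_protein(rint(c(150L, 400L)))
  }

  ## stream 503: tissue counts
  stream_seed(cfg$seed, 503L)
  n_t <- length(cfg$tissues)
  base <- stats::rlnorm(n_members, cfg$base_meanlog, cfg$base_sdlog)
  mult <- matrix(runif(n_members * n_t, cfg$other_multiplier_range[1],
                       cfg$other_multiplier_range[2]),
                 nrow = n_members, dimnames = list(member_ids, cfg$tissues))
  mult[, cfg$calibrator_tissue] <- cfg$root_multiplier
  lib_sizes <- setNames(round(runif(n_t, cfg$lib_size_range[1], cfg$lib_size_range[2])),
                        cfg$tissues)
  lengths_bp <- vapply(gene_models[member_ids], function(gm)
    sum(gm$exons[, 2] - gm$exons[, 1] + 1), numeric(1))
  mu <- base * mult * rep(lib_sizes / 2e6, each = n_members)
  counts_mat <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                       nrow = n_members, dimnames = dimnames(mult))
  counts <- count_matrix(counts_mat, lib_sizes, lengths_bp)

  ## stream 601: qPCR Ct table
  stream_seed(cfg$seed, 601L)
  mikc_members <- member_ids[classes %in% mikc_type_classes()]
  qpcr_genes <- sort(sample(mikc_members, cfg$n_qpcr_genes))
  ct_base <- setNames(runif(cfg$n_qpcr_genes, cfg$ct_base_range[1], cfg$ct_base_range[2]),
                      qpcr_genes)
  ct_rows <- list()
  add_ct <- function(gene, multipliers, base_ct) {
    for (tis in cfg$tissues) for (b in 1:3) for (tr in 1:3) {
      ct_rows[[length(ct_rows) + 1]] <<- data.frame(
        gene = gene, tissue = tis, bio_rep = b, tech_rep = tr,
        ct = base_ct - log2(multipliers[[tis]]) + stats::rnorm(1, 0, cfg$ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  for (g in qpcr_genes) add_ct(g, as.list(mult[g, ]), ct_base[[g]])
  add_ct(cfg$reference_gene, setNames(as.list(rep(1, n_t)), cfg$tissues), 22)
  ct <- do.call(rbind, ct_rows)
  planted_folds <- do.call(rbind, lapply(qpcr_genes, function(g)
    data.frame(gene = g, tissue = cfg$tissues,
               planted_fold = mult[g, ] / mult[g, cfg$calibrator_tissue],
               stringsAsFactors = FALSE, row.names = NULL)))

  manifest <- list(
    seed = cfg$seed,
    members = data.frame(
      id = member_ids, class = classes, domain_offset = domain_offset,
      k_offset = k_offset, has_zipper = has_zipper,
      chromosome = vapply(gene_models[member_ids], `[[`, "", "chromosome"),
      start = vapply(gene_models[member_ids], `[[`, 0, "start"),
      end = vapply(gene_models[member_ids], `[[`, 0, "end"),
      introns = unname(introns[member_ids]), stringsAsFactors = FALSE),
    decoys = decoy_ids,
    truncated = trunc_ids,
    duplicate_pairs = dup_pairs,
    clusters = planted_clusters,
    ortholog_pairs = ortholog_pairs,
    expression = list(base_means = setNames(base, member_ids),
                      multipliers = mult, lib_sizes = lib_sizes),
    qpcr = planted_folds
  )
  audit_manifest(manifest, proteins, gene_models, counts)

  out <- list(config = cfg, proteins = proteins, species_b = species_b,
              gene_models = gene_models, refs = refs, ref_labels = ref_labels,
              seed_mads = seed_mads, seed_k = seed_k, counts = counts,
              ct = ct, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      proteins = file.path(outdir, "proteins.fasta"),
      species_b = file.path(outdir, "species_b.fasta"),
      gff = file.path(outdir, "genome.gff3"),
      seed_mads = file.path(outdir, "mads_seed.sto"),
      seed_k = file.path(outdir, "k_seed.sto"),
      refs = file.path(outdir, "refs.fasta"),
      ref_labels = file.path(outdir, "ref_labels.tsv"),
      counts = file.path(outdir, "counts.tsv"),
      ct = file.path(outdir, "ct.tsv"),
      manifest = file.path(outdir, "manifest.json")
    )
    write_fasta(proteins, paths[["proteins"]])
    write_fasta(species_b, paths[["species_b"]])
    write_gff3(gene_models, paths[["gff"]])
    write_stockholm(seed_mads, paths[["seed_mads"]])
    write_stockholm(seed_k, paths[["seed_k"]])
    write_fasta(refs, paths[["refs"]])
    utils::write.table(data.frame(ref = names(ref_labels), class = ref_labels),
                       paths[["ref_labels"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    write_counts_tsv(counts, paths[["counts"]])
    write_ct_table(ct, paths[["ct"]])
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), paths[["manifest"]])
    out$paths <- paths
  }
  out
}

# internal consistency of the manifest against the emitted objects
audit_manifest <- function(manifest, proteins, gene_models, counts) {
  m <- manifest
  stopifnot(
    all(m$members$id %in% names(proteins)),
    !any(m$decoys %in% m$members$id),
    identical(sort(names(gene_models)),
              sort(c(m$members$id, m$decoys, m$truncated))),
    identical(sort(rownames(counts$counts)), sort(m$members$id)),
    all(m$ortholog_pairs$id_a %in% m$members$id),
    all(abs(m$duplicate_pairs$realized_identity - m$duplicate_pairs$target_identity) <= 0.02 + 1e-9)
  )
  for (cl in m$clusters) {
    chr <- vapply(gene_models[cl$members], `[[`, "", "chromosome")
    stopifnot(all(chr == cl$chromosome))
  }
  invisible(TRUE)
}

#' Write gene models to a GFF3 file
#'
#' One gene, one mRNA and its exons per \code{\link{gene_model}}; the
#' inverse of \code{\link{read_gff3}} for single-transcript genes. Unplaced
#' genes are written on the sentinel sequence \code{chrN}.
#'
#' @param gene_models Named list of \code{gene_model} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(gene_models, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gm in gene_models) {
    chr <- if (is.na(gm$chromosome)) "chrN" else gm$chromosome
    line <- function(type, start, end, attrs)
      sprintf("%s\tgenefamkit\t%s\t%.0f\t%.0f\t.\t%s\t.\t%s",
              chr, type, start, end, gm$strand, attrs)
    writeLines(line("gene", gm$start, gm$end, paste0("ID=", gm$gene_id)), con)
    mrna_id <- paste0(gm$gene_id, ".t1")
    writeLines(line("mRNA", gm$start, gm$end,
                    paste0("ID=", mrna_id, ";Parent=", gm$gene_id)), con)
    for (e in seq_len(nrow(gm$exons))) {
      writeLines(line("exon", gm$exons[e, 1], gm$exons[e, 2],
                      paste0("ID=", mrna_id, ".exon", e, ";Parent=", mrna_id)), con)
    }
  }
  invisible(path)
}
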
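# Synthetic panel generator. Emulates the statistical structure of a
# clonally propagated fruit-crop genotyping panel: ~19 multi-SNP amplicon
# segments with skewed multi-allelic haplotype frequencies (one common
# haplotype plus a tail of rares), a set of distinct base genotypes drawn
# under Hardy-Weinberg, clone families of very unequal size, occasional
# somatic variants (single-segment loss of heterozygosity), and
# parent-offspring pairs built by Mendelian segregation. Truth tables are
# first-class outputs so every downstream stage can be validated against
# the planted structure.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions of the red bayberry reference
#' panel: 19 segments with the published per-segment SNP and haplotype
#' counts (mean 7.8 haplotypes/segment), Dirichlet concentration 0.3 for
#' skewed frequencies (mean minor-allele frequency near 8-9%), 72 base
#' genotypes expanded to 141 accessions with clone-family sizes up to 18,
#' one somatic loss-of-heterozygosity pair, and 10 parent-offspring trios.
#'
#' @param n_segments Number of amplicon segments.
#' @param alleles_per_segment Integer vector of haplotype counts per segment.
#' @param snps_per_segment Integer vector of SNP-site counts per segment.
#' @param copy_number Integer vector (1/2) per segment.
#' @param dirichlet_conc Dirichlet concentration for haplotype frequencies.
#' @param n_base_genotypes Number of distinct genotypes to plant.
#' @param clone_multiplicities Integer vector (length `n_base_genotypes`)
#'   of accessions per genotype.
#' @param n_somatic_pairs Number of planted single-segment LOH pairs.
#' @param n_trios Number of planted parent-offspring trios.
#' @param trace_het_ratio True secondary/primary ratio at heterozygous
#'   trace positions (single-copy segments; duplicated segments use
#'   `trace_het_ratio_dup`).
#' @param trace_het_ratio_dup Ratio for duplicated segments (variant in one
#'   of four gene copies gives a weaker secondary peak).
#' @param trace_noise_sd SD of truncated Gaussian peak noise.
#' @param seed Integer seed making the whole study reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_segments = 19L,
                       alleles_per_segment = c(13L, 14L, 8L, 7L, 4L, 15L, 10L,
                                               8L, 9L, 7L, 7L, 11L, 3L, 2L,
                                               7L, 4L, 7L, 4L, 8L),
                       snps_per_segment = c(17L, 13L, 13L, 13L, 4L, 12L, 15L,
                                            10L, 14L, 6L, 7L, 13L, 4L, 1L,
                                            9L, 5L, 10L, 3L, 7L),
                       copy_number = ifelse(seq_len(n_segments) %in%
                                              c(7L, 11L, 14L, 15L), 2L, 1L),
                       dirichlet_conc = 0.3,
                       n_base_genotypes = 72L,
                       clone_multiplicities = c(18L, 14L, rep(3L, 18L),
                                                rep(2L, 3L), rep(1L, 49L)),
                       n_somatic_pairs = 1L,
                       n_trios = 10L,
                       trace_het_ratio = 0.8,
                       trace_het_ratio_dup = 0.4,
                       trace_noise_sd = 0,
                       seed = 1L) {
  alleles_per_segment <- rep_len(as.integer(alleles_per_segment), n_segments)
  snps_per_segment <- rep_len(as.integer(snps_per_segment), n_segments)
  copy_number <- rep_len(as.integer(copy_number), n_segments)
  stopifnot(all(alleles_per_segment >= 1L), all(snps_per_segment >= 1L),
            all(2^snps_per_segment >= alleles_per_segment),
            n_base_genotypes >= 1L,
            length(clone_multiplicities) == n_base_genotypes,
            all(clone_multiplicities >= 1L),
            n_somatic_pairs >= 0L, n_trios >= 0L,
            n_somatic_pairs + n_trios < n_base_genotypes,
            dirichlet_conc > 0,
            trace_het_ratio > 0, trace_het_ratio <= 1)
  structure(list(n_segments = n_segments,
                 alleles_per_segment = alleles_per_segment,
                 snps_per_segment = snps_per_segment,
                 copy_number = copy_number,
                 dirichlet_conc = dirichlet_conc,
                 n_base_genotypes = as.integer(n_base_genotypes),
                 clone_multiplicities = as.integer(clone_multiplicities),
                 n_somatic_pairs = as.integer(n_somatic_pairs),
                 n_trios = as.integer(n_trios),
                 trace_het_ratio = trace_het_ratio,
                 trace_het_ratio_dup = trace_het_ratio_dup,
                 trace_noise_sd = trace_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# k distinct haplotype sequences of s SNP sites, every site polymorphic
sim_haplotype_seqs <- function(k, s) {
  ref <- sample(c("A", "C", "G", "T"), s, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  repeat {
    codes <- sample.int(2^s, k) - 1L   # distinct by construction
    bits <- t(vapply(codes, function(x) as.integer(intToBits(x))[seq_len(s)],
                     integer(s)))
    if (s == 1L) bits <- matrix(bits, nrow = k)
    poly <- colSums(bits) %in% seq_len(k - 1L)
    if (k == 1L || all(poly)) {
      seqs <- apply(bits, 1L, function(row) {
        paste(ifelse(row == 1L, alt, ref), collapse = "")
      })
      return(seqs)
    }
  }
}

draw_dirichlet <- function(k, conc) {
  repeat {
    g <- stats::rgamma(k, shape = conc)
    if (sum(g) > 0 && all(g > 1e-12 * sum(g))) return(g / sum(g))
  }
}

#' Simulate a complete fingerprinting study
#'
#' Per segment, haplotype frequencies are Dirichlet-skewed and sequences
#' generated over the segment's SNP sites; base genotypes are drawn under
#' Hardy-Weinberg; planted parent-offspring trios replace some base slots
#' with Mendelian offspring of two founders; planted somatic pairs replace
#' a slot with a single-segment loss-of-heterozygosity mutant of another
#' base genotype; clone families replicate base genotypes into the
#' accession panel. Fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study`: `config`, `segments` (a
#'   [segment_table()]), `haplotypes` (per-segment `data.frame` `hap_id`,
#'   `sequence`, `freq`, IDs 1..k in descending frequency), `panel` (the
#'   141-accession-style [hap_panel()]), and `truth` with `templates` (the
#'   base-genotype `hap_panel`), `membership` (accession -> template),
#'   `clone_groups`, `somatic_events`, `trios`, and the generating
#'   frequencies.
#' @export
sim_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_segments
  seg_ids <- paste0("SEG", seq_len(m))
  segments <- segment_table(seg_ids,
                            amplicon_length = 500L + config$snps_per_segment,
                            copy_number = config$copy_number)
  haplotypes <- vector("list", m); names(haplotypes) <- seg_ids
  freqs <- vector("list", m); names(freqs) <- seg_ids
  for (j in seq_len(m)) {
    k <- config$alleles_per_segment[j]
    p <- sort(draw_dirichlet(k, config$dirichlet_conc), decreasing = TRUE)
    seqs <- sim_haplotype_seqs(k, config$snps_per_segment[j])
    haplotypes[[j]] <- data.frame(hap_id = seq_len(k), sequence = seqs,
                                  freq = p, stringsAsFactors = FALSE)
    freqs[[j]] <- stats::setNames(p, seq_len(k))
  }
  nb <- config$n_base_genotypes
  n_founder <- nb - config$n_somatic_pairs - config$n_trios
  draw_profile <- function() {
    a <- integer(m); b <- integer(m)
    for (j in seq_len(m)) {
      pair <- sample.int(config$alleles_per_segment[j], 2L, replace = TRUE,
                         prob = freqs[[j]])
      a[j] <- min(pair); b[j] <- max(pair)
    }
    list(a = a, b = b)
  }
  key_of <- function(pr) paste(pr$a, pr$b, sep = "/", collapse = ";")
  templates <- list(); keys <- character(0)
  while (length(templates) < n_founder) {
    pr <- draw_profile()
    if (key_of(pr) %in% keys) next
    templates[[length(templates) + 1L]] <- pr
    keys <- c(keys, key_of(pr))
  }
  # planted trios: offspring of two distinct founders
  trios <- data.frame(offspring = character(0), parent_a = character(0),
                      parent_b = character(0), stringsAsFactors = FALSE)
  for (t in seq_len(config$n_trios)) {
    repeat {
      pa <- sample.int(n_founder, 2L)
      p1 <- templates[[pa[1]]]; p2 <- templates[[pa[2]]]
      a <- integer(m); b <- integer(m)
      for (j in seq_len(m)) {
        x <- if (stats::runif(1) < 0.5) p1$a[j] else p1$b[j]
        y <- if (stats::runif(1) < 0.5) p2$a[j] else p2$b[j]
        a[j] <- min(x, y); b[j] <- max(x, y)
      }
      off <- list(a = a, b = b)
      if (!(key_of(off) %in% keys)) {
        templates[[length(templates) + 1L]] <- off
        keys <- c(keys, key_of(off))
        trios <- rbind(trios, data.frame(
          offspring = paste0("G", length(templates)),
          parent_a = paste0("G", pa[1]), parent_b = paste0("G", pa[2]),
          stringsAsFactors = FALSE))
        break
      }
    }
  }
  # planted somatic pairs: LOH at one heterozygous segment of a base genotype
  somatic <- data.frame(base = character(0), mutant = character(0),
                        segment_id = character(0), type = character(0),
                        stringsAsFactors = FALSE)
  for (t in seq_len(config$n_somatic_pairs)) {
    repeat {
      src <- sample.int(length(templates), 1L)
      pr <- templates[[src]]
      hets <- which(pr$a != pr$b)
      if (!length(hets)) next
      j <- if (length(hets) == 1L) hets else sample(hets, 1L)
      mut <- pr
      keep <- if (stats::runif(1) < 0.5) pr$a[j] else pr$b[j]
      mut$a[j] <- keep; mut$b[j] <- keep
      if (!(key_of(mut) %in% keys)) {
        templates[[length(templates) + 1L]] <- mut
        keys <- c(keys, key_of(mut))
        somatic <- rbind(somatic, data.frame(
          base = paste0("G", src), mutant = paste0("G", length(templates)),
          segment_id = seg_ids[j], type = "loh", stringsAsFactors = FALSE))
        break
      }
    }
  }
  tmpl_a <- do.call(rbind, lapply(templates, `[[`, "a"))
  tmpl_b <- do.call(rbind, lapply(templates, `[[`, "b"))
  tmpl_ids <- paste0("G", seq_len(nb))
  template_panel <- hap_panel(tmpl_a, tmpl_b, accessions = tmpl_ids,
                              segments = seg_ids)
  mult <- config$clone_multiplicities
  owner <- rep(seq_len(nb), times = mult)
  acc_ids <- sprintf("acc%03d", seq_along(owner))
  panel <- hap_panel(tmpl_a[owner, , drop = FALSE],
                     tmpl_b[owner, , drop = FALSE],
                     accessions = acc_ids, segments = seg_ids)
  structure(list(config = config, segments = segments,
                 haplotypes = haplotypes, panel = panel,
                 truth = list(templates = template_panel,
                              membership = stats::setNames(tmpl_ids[owner], acc_ids),
                              clone_groups = stats::setNames(mult, tmpl_ids),
                              somatic_events = somatic, trios = trios,
                              frequencies = freqs)),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d segments, %d base genotypes, %d accessions (seed %d)\n",
              x$config$n_segments, x$config$n_base_genotypes,
              n_accessions(x$panel), x$config$seed))
  invisible(x)
}

#' Mendelian offspring of two profiles
#'
#' Per segment, one uniformly chosen haplotype from each parent; the pair
#' is stored canonically. The offspring therefore shares at least one
#' haplotype with each parent at every segment.
#'
#' @param parent_a,parent_b Profile tables ([profile_table()] layout) over
#'   the same segments, fully typed.
#' @param seed Optional integer seed.
#' @return A profile table for the offspring.
#' @export
sim_offspring <- function(parent_a, parent_b, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!identical(parent_a$segment_id, parent_b$segment_id)) {
    stop("parents must cover the same segments in the same order")
  }
  if (anyNA(parent_a$hap_a) || anyNA(parent_b$hap_a)) {
    stop("parents must be fully typed")
  }
  m <- nrow(parent_a)
  pick1 <- ifelse(stats::runif(m) < 0.5, parent_a$hap_a, parent_a$hap_b)
  pick2 <- ifelse(stats::runif(m) < 0.5, parent_b$hap_a, parent_b$hap_b)
  data.frame(segment_id = parent_a$segment_id,
             hap_a = pmin(pick1, pick2), hap_b = pmax(pick1, pick2),
             stringsAsFactors = FALSE)
}

#' Simulate a Sanger-style peak trace for a diploid amplicon
#'
#' At positions where the two haplotypes agree, the primary peak carries
#' (noisy) unit signal and the secondary peak is near zero; where they
#' differ, the secondary peak carries `het_ratio` of the primary signal.
#' Noise is truncated Gaussian (signals stay non-negative and the secondary
#' never exceeds the primary).
#'
#' @param hap_a_seq,hap_b_seq Equal-length haplotype sequences (A/C/G/T).
#' @param het_ratio True secondary/primary ratio at heterozygous positions,
#'   in (0, 1].
#' @param noise_sd SD of the truncated Gaussian signal noise (default 0).
#' @param seed Optional integer seed.
#' @return A [peak_trace()].
#' @export
sim_traces <- function(hap_a_seq, hap_b_seq, het_ratio = 0.8, noise_sd = 0,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nchar(hap_a_seq) != nchar(hap_b_seq)) stop("haplotype length mismatch")
  if (!(het_ratio > 0 && het_ratio <= 1)) stop("het_ratio must lie in (0, 1]")
  a <- strsplit(hap_a_seq, "")[[1]]
  b <- strsplit(hap_b_seq, "")[[1]]
  n <- length(a)
  het <- a != b
  primary <- ifelse(het, pmin(a, b), a)
  secondary <- ifelse(het, pmax(a, b),
                      vapply(a, function(x) {
                        sample(setdiff(c("A", "C", "G", "T"), x), 1L)
                      }, ""))
  p_sig <- pmax(1 + stats::rnorm(n, 0, noise_sd), 1e-6)
  s_sig <- ifelse(het,
                  pmax(het_ratio + stats::rnorm(n, 0, noise_sd), 0),
                  pmax(stats::rnorm(n, 0, noise_sd), 0))
  s_sig <- pmin(s_sig, p_sig)
  peak_trace(seq_len(n), primary, p_sig, secondary, s_sig)
}
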
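# paired bisulfite read simulation with full truth labels

reassemble_strings <- function(flat, lens) {
  cs <- cumsum(lens)
  st <- cs - lens + 1L
  substring(paste(flat, collapse = ""), st, cs)
}

apply_seq_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  flat <- unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit)) {
    cur <- match(flat[hit], BASES)
    cur[is.na(cur)] <- 1L
    flat[hit] <- BASES[((cur - 1L + sample.int(3L, length(hit),
                                               replace = TRUE)) %% 4L) + 1L]
  }
  reassemble_strings(flat, lens)
}

#' Truth set for a simulated sample
#'
#' @param reads data.frame: id, allele, strand, chrom, start, end per
#'   simulated read pair.
#' @param sites data.frame: chrom, pos, allele, prob (assigned methylation
#'   probability), n_frag and n_meth (realized molecule counts among
#'   sequenced fragments).
#' @param regions planted differential regions (chrom, start, end, class,
#'   genotype, direction, effect).
#' @return object of class \code{truth_set}.
#' @export
truth_set <- function(reads, sites, regions) {
  if (anyDuplicated(reads$id)) stop("read ids must be unique in a truth set")
  structure(list(reads = reads, sites = sites, regions = regions),
            class = "truth_set")
}

#' Simulate paired-end bisulfite reads
#'
#' Draws fragments along the diploid genome at the configured per-CpG
#' fragment depth, picks an allele (Bernoulli 1/2) and an original strand
#' per fragment, realizes per-molecule CpG methylation states from the
#' methylome probabilities, applies bisulfite chemistry (unmethylated C
#' reads T with \code{conversion_rate}; methylated C reads T with
#' \code{failed_conversion_rate}; non-CpG cytosines are treated as
#' unmethylated) and per-base sequencing errors, and emits directional
#' paired reads (complementary CTOT/CTOB strands under \code{pbat}).
#' Read names carry the truth as \code{id|allele|strand|chrom|start}.
#'
#' @param genome1,genome2 the two haplotype genomes (identical coordinates).
#' @param methylome result of \code{\link{assign_methylome}}.
#' @param config \code{\link{sim_config}}.
#' @param genotype genotype column of the methylome to realize.
#' @param seed seed for this sample's reads (replicates use distinct seeds).
#' @param id_prefix prefix for read ids.
#' @return list(reads, truth): \code{reads} is a data.table with id, name,
#'   seq1, seq2, qual1, qual2; \code{truth} a \code{\link{truth_set}}.
#' @export
simulate_read_pairs <- function(genome1, genome2, methylome, config,
                                genotype = config$genotype,
                                seed = config$seed, id_prefix = "r") {
  set.seed(seed)
  L <- config$read_length
  lens <- genome1$length
  total <- sum(as.numeric(lens))
  N <- round(config$coverage * total / config$fragment_mean)
  planted <- attr(methylome, "planted")
  planted <- planted[planted$genotype == genotype, , drop = FALSE]
  if (N == 0L) {
    empty_reads <- data.table::data.table(id = character(0),
      name = character(0), seq1 = character(0), seq2 = character(0),
      qual1 = character(0), qual2 = character(0))
    return(list(reads = empty_reads,
                truth = truth_set(
                  data.frame(id = character(0), allele = integer(0),
                             strand = character(0), chrom = character(0),
                             start = integer(0), end = integer(0)),
                  data.frame(chrom = character(0), pos = integer(0),
                             allele = integer(0), prob = numeric(0),
                             n_frag = integer(0), n_meth = integer(0)),
                  planted)))
  }
  chrom <- sample(names(lens), N, replace = TRUE, prob = as.numeric(lens))
  flen <- as.integer(pmax(L, round(rnorm(N, config$fragment_mean,
                                         config$fragment_sd))))
  flen <- pmin(flen, unname(lens[chrom]))
  start <- as.integer(floor(runif(N) * (unname(lens[chrom]) - flen + 1L)))
  frag <- data.table::data.table(
    fid = seq_len(N),
    id = sprintf("%s%07d", id_prefix, seq_len(N)),
    chrom = chrom, start = start, end = start + flen,
    allele = 1L + rbinom(N, 1L, 0.5),
    sbase = c("OT", "OB")[1L + rbinom(N, 1L, 0.5)])
  frag[, strand := if (config$pbat) c(OT = "CTOT", OB = "CTOB")[sbase]
       else sbase]

  genomes <- list(genome1, genome2)
  # methylatable sites per allele: methylome sites still intact in that genome
  cpg2 <- index_cpg_sites(genome2)
  site_sets <- list()
  for (a in 1:2) for (ch in names(lens)) {
    s_all <- methylome[chrom == ch, pos]
    site_sets[[paste(a, ch)]] <-
      if (a == 1L) s_all else intersect(s_all, cpg2[[ch]])
  }

  # realize per-molecule CpG states for the sites each strand can observe
  state_rows <- list()
  for (a in 1:2) for (ch in unique(frag$chrom)) {
    S <- site_sets[[paste(a, ch)]]
    if (length(S) == 0L) next
    sub <- frag[allele == a & chrom == ch]
    if (nrow(sub) == 0L) next
    ws <- ifelse(sub$sbase == "OT", sub$start, sub$start - 1L)
    we <- ifelse(sub$sbase == "OT", sub$end - 1L, sub$end - 2L)
    lo <- findInterval(ws - 1L, S) + 1L
    hi <- findInterval(we, S)
    nn <- pmax(0L, hi - lo + 1L)
    keep <- nn > 0L
    if (!any(keep)) next
    idx <- sequence(nn[keep]) + rep(lo[keep] - 1L, nn[keep])
    state_rows[[paste(a, ch)]] <- data.table::data.table(
      fid = rep(sub$fid[keep], nn[keep]), chrom = ch,
      site = S[idx], allele = a)
  }
  states <- if (length(state_rows)) data.table::rbindlist(state_rows) else
    data.table::data.table(fid = integer(0), chrom = character(0),
                           site = integer(0), allele = integer(0))
  if (nrow(states)) {
    states[, prob := 0]
    for (a in 1:2) {
      ii <- which(states$allele == a)
      if (!length(ii)) next
      keys <- data.table::data.table(chrom = states$chrom[ii],
                                     pos = states$site[ii])
      data.table::set(states, i = ii, j = "prob",
                      value = site_probability(methylome, keys, genotype, a,
                                               config))
    }
    states[, state := rbinom(.N, 1L, prob)]
    data.table::setkeyv(states, c("fid", "site"))
  } else {
    states[, `:=`(prob = numeric(0), state = integer(0))]
  }

  truth_sites <- if (nrow(states))
    states[, .(prob = prob[1L], n_frag = .N, n_meth = sum(state)),
           by = .(chrom, pos = site, allele)][order(chrom, pos, allele)]
  else data.frame(chrom = character(0), pos = integer(0),
                  allele = integer(0), prob = numeric(0),
                  n_frag = integer(0), n_meth = integer(0))

  # bisulfite chemistry + read slicing, per original strand
  frag[, `:=`(r1 = NA_character_, r2 = NA_character_)]
  for (sb in c("OT", "OB")) {
    sub_i <- which(frag$sbase == sb)
    if (!length(sub_i)) next
    sub <- frag[sub_i]
    top <- character(nrow(sub))
    for (a in 1:2) for (ch in unique(sub$chrom)) {
      jj <- which(sub$allele == a & sub$chrom == ch)
      if (!length(jj)) next
      top[jj] <- substring(genomes[[a]]$seq[[ch]],
                           sub$start[jj] + 1L, sub$end[jj])
    }
    mol <- if (sb == "OT") top else revcomp(top)
    mlen <- nchar(mol)
    flat <- unlist(strsplit(mol, "", fixed = TRUE), use.names = FALSE)
    fidx <- rep(seq_len(nrow(sub)), mlen)
    off <- sequence(mlen) - 1L
    gpos <- if (sb == "OT") sub$start[fidx] + off else
      sub$end[fidx] - 1L - off
    cidx <- which(flat == "C")
    if (length(cidx)) {
      sitepos <- if (sb == "OT") gpos[cidx] else gpos[cidx] - 1L
      st <- states[data.table::data.table(fid = sub$fid[fidx[cidx]],
                                          site = sitepos),
                   on = c("fid", "site")]$state
      u <- runif(length(cidx))
      toT <- ifelse(is.na(st), u < config$conversion_rate,
                    ifelse(st == 1L, u < config$failed_conversion_rate,
                           u < config$conversion_rate))
      flat[cidx[toT]] <- "T"
    }
    molc <- reassemble_strings(flat, mlen)
    r1 <- substr(molc, 1L, L)
    r2 <- revcomp(substring(molc, mlen - L + 1L, mlen))
    data.table::set(frag, i = sub_i, j = "r1", value = r1)
    data.table::set(frag, i = sub_i, j = "r2", value = r2)
  }
  if (config$pbat) {
    tmp <- frag$r1
    frag[, r1 := r2]
    frag[, r2 := tmp]
  }

  # PCR-style duplicates (identical molecules, fresh sequencing errors)
  if (config$duplicate_rate > 0) {
    dup <- frag[runif(.N) < config$duplicate_rate]
    if (nrow(dup)) {
      dup[, id := paste0(id, ".dup")]
      frag <- data.table::rbindlist(list(frag, dup))
    }
  }
  frag[, `:=`(r1 = apply_seq_errors(r1, config$seq_error_rate),
              r2 = apply_seq_errors(r2, config$seq_error_rate))]
  qual <- strrep(rawToChar(as.raw(config$const_qual + 33L)), L)
  frag[, name := paste(id, allele, strand, chrom, start, sep = "|")]

  reads <- frag[, .(id, name, seq1 = r1, seq2 = r2,
                    qual1 = qual, qual2 = qual)]
  truth <- truth_set(
    as.data.frame(frag[, .(id, allele, strand, chrom, start, end)]),
    as.data.frame(truth_sites), planted)
  list(reads = reads, truth = truth)
}

#' Oracle alignments from simulation truth
#'
#' Converts simulated reads plus their truth labels into an
#' \code{aligned_pairs} table at the true positions (a perfect-aligner
#' oracle).  Lets extraction and downstream stages be exercised and timed
#' independently of the aligner.
#'
#' @param reads reads table from \code{\link{simulate_read_pairs}}.
#' @param truth the matching \code{\link{truth_set}}.
#' @return an \code{aligned_pairs} data.table (source = "truth").
#' @export
pairs_from_truth <- function(reads, truth) {
  m <- merge(data.table::as.data.table(reads),
             data.table::as.data.table(truth$reads), by = "id")
  if (nrow(m) < nrow(reads))
    stop("reads contain ids absent from the truth set")
  L <- if (nrow(m)) nchar(m$seq1[1L]) else 0L
  right <- m$end - L
  rev1 <- m$strand %in% c("OB", "CTOT")
  out <- data.table::data.table(
    id = m$id, chrom = m$chrom,
    start1 = as.integer(ifelse(rev1, right, m$start)),
    start2 = as.integer(ifelse(rev1, m$start, right)),
    orient1 = ifelse(rev1, "R", "F"), orient2 = ifelse(rev1, "F", "R"),
    strand = m$strand, mm1 = 0L, mm2 = 0L, mapped = TRUE, unique = TRUE,
    read_len = L, seq1 = m$seq1, seq2 = m$seq2,
    qual1 = m$qual1, qual2 = m$qual2, source = "truth")
  data.table::setattr(out, "class",
                      c("aligned_pairs", class(data.table::data.table())))
  out
}

#' Write / read paired FASTQ
#'
#' Phred+33, gzipped; read names carry the simulation truth labels.
#'
#' @param reads reads table from \code{\link{simulate_read_pairs}}.
#' @param prefix output prefix; files \code{<prefix>_1.fastq.gz} and
#'   \code{<prefix>_2.fastq.gz} are written.
#' @return the two file paths (invisibly for the writer).
#' @export
write_fastq_pairs <- function(reads, prefix) {
  files <- paste0(prefix, c("_1.fastq.gz", "_2.fastq.gz"))
  for (m in 1:2) {
    ss <- Biostrings::DNAStringSet(reads[[paste0("seq", m)]])
    names(ss) <- reads$name
    q <- Biostrings::BStringSet(reads[[paste0("qual", m)]])
    Biostrings::writeXStringSet(ss, files[m], format = "fastq",
                                compress = TRUE, qualities = q)
  }
  invisible(files)
}

#' @param file1,file2 FASTQ paths for mate 1 and mate 2.
#' @rdname write_fastq_pairs
#' @export
read_fastq_pairs <- function(file1, file2) {
  s1 <- Biostrings::readDNAStringSet(file1, format = "fastq",
                                     with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(file2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(s1) != length(s2)) stop("mate files differ in read count")
  nm <- sub("\\s.*$", "", names(s1))
  data.table::data.table(
    id = sub("\\|.*$", "", nm), name = nm,
    seq1 = as.character(s1), seq2 = as.character(s2),
    qual1 = as.character(S4Vectors::mcols(s1)$qualities),
    qual2 = as.character(S4Vectors::mcols(s2)$qualities))
}

#' Simulate per-CpG count tables directly (no reads)
#'
#' Count-level mode of the generator: per replicate, site depth is Poisson
#' with the given mean and methylated counts are beta-binomial around the
#' methylome probability with dispersion \code{phi}.  Used for
#' statistics-focused experiments where read-level chemistry is not under
#' test.
#'
#' @param methylome a \code{\link{assign_methylome}} result.
#' @param genotype genotype column to realize.
#' @param coverage mean per-site depth per replicate.
#' @param phi beta-binomial overdispersion (0 gives pure binomial).
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @param sample_prefix sample label prefix.
#' @return list of \code{\link{cpg_count_table}}, one per replicate.
#' @export
simulate_count_tables <- function(methylome, genotype, coverage, phi = 0,
                                  n_rep = 1L, seed = 1L,
                                  sample_prefix = genotype) {
  set.seed(seed)
  p <- methylome[[paste0("p_", genotype)]]
  S <- nrow(methylome)
  lapply(seq_len(n_rep), function(r) {
    n <- rpois(S, coverage)
    pr <- if (phi > 0)
      rbeta(S, p * (1 - phi) / phi, (1 - p) * (1 - phi) / phi) else p
    k <- rbinom(S, n, pr)
    cpg_count_table(data.frame(chrom = methylome$chrom, pos = methylome$pos,
                               meth = k, unmeth = n - k),
                    sample = paste0(sample_prefix, "_rep", r))
  })
}

#' Compare pipeline results against simulation truth
#'
#' Dispatches on the result type: allele assignments give assignment
#' accuracy and rate; count tables give per-site mean absolute error both
#' against the realized molecule-level methylated fraction
#' (\code{mae_realized}) and against the assigned Beta probability
#' (\code{mae_probability}); called region sets give precision, recall and
#' base-pair Jaccard against the planted regions.
#'
#' @param result an \code{allelic_assignment}, \code{cpg_count_table}, or a
#'   data.frame of called regions (chrom/start/end).
#' @param truth the matching \code{\link{truth_set}}.
#' @param planted planted regions to compare region calls against (defaults
#'   to all of \code{truth$regions}).
#' @return named list of metrics.
#' @export
evaluate_against_truth <- function(result, truth,
                                   planted = truth$regions) {
  stopifnot(inherits(truth, "truth_set"))
  if (inherits(result, "allelic_assignment")) {
    if (!all(result$id %in% truth$reads$id))
      stop("result contains read ids absent from the truth set")
    m <- merge(as.data.frame(result), truth$reads[, c("id", "allele")],
               by = "id")
    assigned <- m$verdict %in% c("genome1", "genome2")
    acc <- if (any(assigned))
      mean(ifelse(m$verdict[assigned] == "genome1", 1L, 2L) ==
             m$allele[assigned]) else NA_real_
    return(list(accuracy = acc, assignment_rate = mean(assigned),
                n_assigned = sum(assigned), n_total = nrow(m)))
  }
  if (inherits(result, "cpg_count_table")) {
    ts <- data.table::as.data.table(truth$sites)
    agg <- ts[, .(prob = sum(prob * n_frag) / sum(n_frag),
                  realized = sum(n_meth) / sum(n_frag)),
              by = .(chrom, pos)]
    tab <- data.table::as.data.table(as.data.frame(result))
    m <- merge(tab, agg, by = c("chrom", "pos"))
    lvl <- m$meth / (m$meth + m$unmeth)
    return(list(mae_realized = mean(abs(lvl - m$realized)),
                mae_probability = mean(abs(lvl - m$prob)),
                n_sites = nrow(m)))
  }
  if (is.data.frame(result) && all(c("chrom", "start", "end") %in%
                                   names(result))) {
    called <- as.data.frame(result)[, c("chrom", "start", "end")]
    pl <- as.data.frame(planted)[, c("chrom", "start", "end")]
    if (nrow(called) == 0L)
      return(list(precision = NA_real_, recall = 0,
                  jaccard = if (nrow(pl)) 0 else NA_real_))
    gc_ <- intervals_to_granges(called)
    gp <- intervals_to_granges(pl)
    ov <- GenomicRanges::findOverlaps(gc_, gp)
    precision <- length(unique(S4Vectors::queryHits(ov))) / length(gc_)
    recall <- if (length(gp))
      length(unique(S4Vectors::subjectHits(ov))) / length(gp) else NA_real_
    return(list(precision = precision, recall = recall,
                jaccard = interval_jaccard(called, pl)))
  }
  stop("unsupported result type for truth evaluation")
}
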
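# Synthetic reference construction: a background genome with UCOS-like
# single-copy genes and mutated TE copies spliced in at recorded positions,
# plus complete ground truth for parameter-recovery tests.

#' Build a synthetic genome with known TE content
#'
#' Generates an i.i.d. random background sequence, draws (or accepts) a
#' consensus for every TE family, and splices `copy_number` mutated copies of
#' each consensus plus one copy of every UCOS gene into the background at
#' random, non-overlapping insertion points. Copies differ from their
#' consensus at a Binomial(consensus_length, per_copy_divergence) number of
#' sites and are inserted on a random strand. Because copies are inserted
#' rather than overwritten, genome size grows with TE content and the
#' single-copy space is left intact, which keeps UCOS depth normalization
#' exact.
#'
#' @param specs List of [family_spec()] objects.
#' @param n_ucos Number of single-copy UCOS-like genes.
#' @param ucos_length Length of each UCOS gene (bp).
#' @param background_length Length of the random background (bp).
#' @param seed Integer seed; the build is fully deterministic given it.
#' @param ucos Optional named character vector of UCOS gene sequences to
#'   insert (one copy each) instead of drawing `n_ucos` random genes; use
#'   this to share a single UCOS reference across simulated accessions.
#' @return A `synthetic_reference` list: `genome` (character), `te_consensus`
#'   and `ucos` (named character vectors), `features` (per-consensus feature
#'   intervals, 0-based half-open), and `truth` (placements, per-family truth,
#'   UCOS coordinates, `genome_size`).
#' @export
build_reference <- function(specs, n_ucos = 20, ucos_length = 1000,
                            background_length = 1e6, seed = 1, ucos = NULL) {
  if (!is.null(ucos)) {
    n_ucos <- length(ucos)
    ucos_length <- if (n_ucos > 0) max(nchar(ucos)) else 1
  }
  if (length(specs) == 0) stop_validation("specs must be non-empty")
  if (inherits(specs, "family_spec")) specs <- list(specs)
  ids <- vapply(specs, `[[`, "", "family_id")
  if (anyDuplicated(ids)) stop_validation("duplicate family_id: ",
                                          ids[duplicated(ids)][1])
  if (n_ucos < 0 || ucos_length <= 0 || background_length <= 0)
    stop_validation("counts and lengths must be positive")
  total_insert <- sum(vapply(specs, function(s)
    as.numeric(s$copy_number) * s$consensus_length, 0)) +
    (if (is.null(ucos)) as.numeric(n_ucos) * ucos_length
     else sum(nchar(ucos)))
  if (total_insert > background_length)
    stop_validation("total requested insert length (", total_insert,
                    " bp) exceeds background_length (", background_length, " bp)")

  set.seed(seed)
  background <- random_dna(background_length)

  te_consensus <- vapply(specs, function(s) {
    if (!is.null(s$consensus)) return(toupper(s$consensus))
    if (s$te_class == "satellite") {
      monomer <- random_dna(s$monomer_length)
      substr(paste(rep(monomer, ceiling(s$consensus_length / s$monomer_length)),
                   collapse = ""), 1, s$consensus_length)
    } else {
      random_dna(s$consensus_length)
    }
  }, "")
  names(te_consensus) <- ids

  if (is.null(ucos)) {
    ucos <- character(0)
    if (n_ucos > 0) {
      ucos <- vapply(seq_len(n_ucos), function(i) random_dna(ucos_length), "")
      names(ucos) <- sprintf("ucos_%03d", seq_len(n_ucos))
    }
  } else {
    ucos <- toupper(ucos)
    if (is.null(names(ucos))) stop_validation("explicit ucos must be named")
  }

  ## one insert record per TE copy and per UCOS gene
  ins_family <- character(0); ins_type <- character(0); ins_seq <- character(0)
  ins_nmut <- integer(0); ins_strand <- character(0); ins_id <- character(0)
  for (s in specs) {
    if (s$copy_number == 0) next
    cons <- te_consensus[[s$family_id]]
    for (ci in seq_len(s$copy_number)) {
      mut <- mutate_sequence(cons, s$per_copy_divergence)
      strand <- sample(c("+", "-"), 1)
      ins_family <- c(ins_family, s$family_id)
      ins_type <- c(ins_type, "TE")
      ins_seq <- c(ins_seq, if (strand == "+") mut$sequence else revcomp(mut$sequence))
      ins_nmut <- c(ins_nmut, mut$n_mut)
      ins_strand <- c(ins_strand, strand)
      ins_id <- c(ins_id, sprintf("%s_copy%03d", s$family_id, ci))
    }
  }
  for (u in names(ucos)) {
    ins_family <- c(ins_family, u); ins_type <- c(ins_type, "UCOS")
    ins_seq <- c(ins_seq, ucos[[u]]); ins_nmut <- c(ins_nmut, 0L)
    ins_strand <- c(ins_strand, "+"); ins_id <- c(ins_id, u)
  }

  n_ins <- length(ins_seq)
  placements <- data.frame(element_id = character(0), family_id = character(0),
                           type = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           n_mut = integer(0), stringsAsFactors = FALSE)
  if (n_ins > 0) {
    pts <- sort(sample.int(background_length, n_ins))
    ord <- sample.int(n_ins) # which insert lands at which point
    lens <- nchar(ins_seq)[ord]
    offset <- c(0, cumsum(lens))[seq_len(n_ins)]
    starts <- pts + offset # 0-based genome coordinates (pts is 1-based cut after pos)
    pieces <- character(2 * n_ins + 1)
    prev <- 0L
    for (i in seq_len(n_ins)) {
      pieces[2 * i - 1] <- substr(background, prev + 1L, pts[i])
      pieces[2 * i] <- ins_seq[ord[i]]
      prev <- pts[i]
    }
    pieces[2 * n_ins + 1] <- substr(background, prev + 1L, background_length)
    genome <- paste(pieces, collapse = "")
    placements <- data.frame(
      element_id = ins_id[ord], family_id = ins_family[ord],
      type = ins_type[ord], start = as.integer(starts),
      end = as.integer(starts + lens), strand = ins_strand[ord],
      n_mut = ins_nmut[ord], stringsAsFactors = FALSE
    )
  } else {
    genome <- background
  }

  features <- do.call(rbind, lapply(specs, function(s) {
    fl <- s$feature_layout
    if (nrow(fl) == 0) return(NULL)
    data.frame(contig_id = s$family_id, feature = fl$feature,
               start = fl$start, end = fl$end, stringsAsFactors = FALSE)
  }))
  if (is.null(features))
    features <- data.frame(contig_id = character(0), feature = character(0),
                           start = integer(0), end = integer(0),
                           stringsAsFactors = FALSE)

  families <- data.frame(
    family_id = ids,
    te_class = vapply(specs, `[[`, "", "te_class"),
    superfamily = vapply(specs, `[[`, "", "superfamily"),
    consensus_length = vapply(specs, `[[`, 0L, "consensus_length"),
    copy_number = vapply(specs, `[[`, 0L, "copy_number"),
    per_copy_divergence = vapply(specs, `[[`, 0, "per_copy_divergence"),
    stringsAsFactors = FALSE
  )
  ucos_df <- placements[placements$type == "UCOS",
                        c("element_id", "start", "end"), drop = FALSE]
  names(ucos_df)[1] <- "ucos_id"
  rownames(ucos_df) <- NULL

  truth <- structure(list(placements = placements, families = families,
                          ucos = ucos_df, genome_size = nchar(genome)),
                     class = "truth_set")
  structure(list(genome = genome, te_consensus = te_consensus, ucos = ucos,
                 features = features, truth = truth, seed = seed),
            class = "synthetic_reference")
}

#' Mutate a sequence by i.i.d. substitutions
#'
#' The number of substituted sites is Binomial(length, divergence); each
#' substituted site receives a uniformly chosen different base.
#'
#' @param sequence DNA string.
#' @param divergence Per-site substitution probability.
#' @return List with `sequence` and `n_mut`.
#' @export
mutate_sequence <- function(sequence, divergence) {
  L <- nchar(sequence)
  n_mut <- rbinom(1, L, divergence)
  if (n_mut == 0) return(list(sequence = sequence, n_mut = 0L))
  pos <- sample.int(L, n_mut)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  old <- match(chars[pos], DNA_BASES) - 1L
  new <- (old + sample.int(3, n_mut, replace = TRUE)) %% 4L
  chars[pos] <- DNA_BASES[new + 1L]
  list(sequence = paste(chars, collapse = ""), n_mut = as.integer(n_mut))
}

#' Write a truth set to a tab-separated file
#'
#' Long-format TSV with a `record` column (`family`, `placement`, `ucos`) and
#' a `genome_size` metadata header; [read_truth()] round-trips it exactly.
#'
#' @param truth A `truth_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  fam <- truth$families
  pl <- truth$placements
  uc <- truth$ucos
  cols <- c("record", "family_id", "te_class", "superfamily",
            "consensus_length", "copy_number", "per_copy_divergence",
            "element_id", "type", "start", "end", "strand", "n_mut")
  blank <- function(n) rep(NA, n)
  fam_rows <- data.frame(record = rep("family", nrow(fam)), fam,
                         element_id = blank(nrow(fam)), type = blank(nrow(fam)),
                         start = blank(nrow(fam)), end = blank(nrow(fam)),
                         strand = blank(nrow(fam)), n_mut = blank(nrow(fam)),
                         stringsAsFactors = FALSE)
  pl_rows <- data.frame(record = rep("placement", nrow(pl)),
                        family_id = pl$family_id, te_class = blank(nrow(pl)),
                        superfamily = blank(nrow(pl)),
                        consensus_length = blank(nrow(pl)),
                        copy_number = blank(nrow(pl)),
                        per_copy_divergence = blank(nrow(pl)),
                        element_id = pl$element_id, type = pl$type,
                        start = pl$start, end = pl$end, strand = pl$strand,
                        n_mut = pl$n_mut, stringsAsFactors = FALSE)
  uc_rows <- data.frame(record = rep("ucos", nrow(uc)),
                        family_id = blank(nrow(uc)), te_class = blank(nrow(uc)),
                        superfamily = blank(nrow(uc)),
                        consensus_length = blank(nrow(uc)),
                        copy_number = blank(nrow(uc)),
                        per_copy_divergence = blank(nrow(uc)),
                        element_id = uc$ucos_id, type = blank(nrow(uc)),
                        start = uc$start, end = uc$end, strand = blank(nrow(uc)),
                        n_mut = blank(nrow(uc)), stringsAsFactors = FALSE)
  out <- rbind(fam_rows[cols], pl_rows[cols], uc_rows[cols])
  write_tsv(out, path, meta = list(genome_size = truth$genome_size))
}

#' Read a truth set written by [write_truth()]
#'
#' @param path Truth TSV file.
#' @return A `truth_set`.
#' @export
read_truth <- function(path) {
  first <- readLines(path, n = 1)
  gs <- as.integer(sub("^# genome_size: ", "", first))
  df <- read_tsv(path)
  fam <- df[df$record == "family",
            c("family_id", "te_class", "superfamily", "consensus_length",
              "copy_number", "per_copy_divergence"), drop = FALSE]
  pl <- df[df$record == "placement",
           c("element_id", "family_id", "type", "start", "end", "strand",
             "n_mut"), drop = FALSE]
  uc <- df[df$record == "ucos", c("element_id", "start", "end"), drop = FALSE]
  names(uc)[1] <- "ucos_id"
  fam$consensus_length <- as.integer(fam$consensus_length)
  fam$copy_number <- as.integer(fam$copy_number)
  for (cc in c("start", "end", "n_mut")) pl[[cc]] <- as.integer(pl[[cc]])
  for (cc in c("start", "end")) uc[[cc]] <- as.integer(uc[[cc]])
  rownames(fam) <- rownames(pl) <- rownames(uc) <- NULL
  structure(list(placements = pl, families = fam, ucos = uc, genome_size = gs),
            class = "truth_set")
}
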
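# Builds the packaged reference signature matrices under inst/extdata/.
# The profiles are deterministic, stylized analogues of the published
# signatures' qualitative definitions (see ?reference_signatures); they are
# synthetic and are the same profiles the cohort simulator draws from.

sbs_channels <- function() {
  cls <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  b <- c("A", "C", "G", "T")
  unlist(lapply(cls, function(cl) {
    ref <- substr(cl, 1, 1)
    as.vector(t(outer(b, b, function(p5, p3) paste0(p5, "[", cl, "]", p3))))
  }))
}

indel_channels <- function() {
  as.vector(t(outer(c("ins", "del"), as.vector(t(outer(
    c("A", "T", "CG", "MULTI"), c("r1", "r2_4", "r5+"), paste, sep = ":"
  ))), paste, sep = ":")))
}

ch <- sbs_channels()
cls_of <- sub(".*\\[(.*)\\].*", "\\1", ch)
p3_of <- substr(ch, 7, 7)

sbs1 <- numeric(96)
cpg <- cls_of == "C>T" & p3_of == "G"
sbs1[cpg] <- 0.9 / sum(cpg)
sbs1[!cpg] <- 0.1 / sum(!cpg)

w5 <- c("C>A" = 0.12, "C>G" = 0.08, "C>T" = 0.20, "T>A" = 0.10, "T>C" = 0.38, "T>G" = 0.12)
sbs5 <- as.numeric(w5[cls_of] / 16)

sbs6 <- numeric(96)
sbs6[cpg] <- 0.35 / sum(cpg)
ct_non <- cls_of == "C>T" & !cpg
sbs6[ct_non] <- 0.35 / sum(ct_non)
tc <- cls_of == "T>C"
sbs6[tc] <- 0.20 / sum(tc)
rest <- !(cpg | ct_non | tc)
sbs6[rest] <- 0.10 / sum(rest)

sbs <- data.frame(channel = ch, SBS1 = sbs1, SBS5 = sbs5, SBS6 = sbs6)

ich <- indel_channels()
set_id <- function(x) setNames(numeric(24), ich)
id1 <- set_id()
id1[c("ins:A:r5+", "ins:T:r5+")] <- 0.425
id1[c("ins:A:r2_4", "ins:T:r2_4")] <- 0.05
id1[c("ins:A:r1", "ins:T:r1")] <- 0.025
id2 <- setNames(id1[sub("^ins", "ins", names(id1))], names(id1)) * 0
id2[c("del:A:r5+", "del:T:r5+")] <- 0.425
id2[c("del:A:r2_4", "del:T:r2_4")] <- 0.05
id2[c("del:A:r1", "del:T:r1")] <- 0.025
id7 <- set_id()
id7[c("del:A:r2_4", "del:T:r2_4")] <- 0.2
id7[c("del:A:r5+", "del:T:r5+")] <- 0.15
id7[c("del:CG:r1", "del:CG:r2_4")] <- 0.05
id7["del:MULTI:r1"] <- 0.15
id7[c("ins:A:r1", "ins:T:r1")] <- 0.025

ids <- data.frame(channel = ich, ID1 = as.numeric(id1), ID2 = as.numeric(id2),
                  ID7 = as.numeric(id7))

stopifnot(abs(colSums(sbs[-1]) - 1) < 1e-12, abs(colSums(ids[-1]) - 1) < 1e-12)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(sbs, "inst/extdata/sbs_signatures_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ids, "inst/extdata/id_signatures_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
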
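## alphabet constants shared across modules (defined first in collation)

BASES <- c("A", "C", "G", "T")

DINUCS <- as.vector(outer(BASES, BASES, paste0))  # 16 XY, X = 3rd, Y = 1st
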
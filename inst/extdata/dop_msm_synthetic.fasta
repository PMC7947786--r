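>dop_synthetic synthetic Dop-like base sequence (planted wild-type residues at documented positions)
VAAPNFGSVHGMSRCSHHMPNTRQCRSLKQVVQSWACPLRDYAHGAFTVAREPGCDMVYQ
MWYDDCIAKDGYIQIGYEVCAAQKICYHHMQVIVSHAFELYSAPFKGICMIDPAHNKWLA
ANHWGGRWSAWDTERAIHCMKVMSKIQARGFKTATLPCCYAIWEYNMLNVASFSDIMPNA
QPMAAKIDCGIQGTATTEPHMNYQYLMWYIEVEHGLEMFLKEKGRHNLNWWGIYTPRKFN
DNVGYQNHMATLCPDFYRCQRGAGKCQMWPAPYHFRHTNPNMTIFGKFYDAMSHFIYGRP
MWNNIGPFRQQIFCQNFVNWYRPEAACHPHPTAYMVHEFGNDAEPENFKVGYIQYYSAGD
WTWQKHTQCQMCYMRTMIEKWCYKCLSEYKVPQCMLGTSSKIKFQPSISFRGYAKPSFTE
EWVQHVYNTEVMFPEFWENMKNVCFSMGASVKQRCIKCHQCMNEQNMYLSGTAHA
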
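>P01112_HRAS_HUMAN transcribed copy of the canonical UniProt record; verify against UniProt when online
MTEYKLVVVGAGGVGKSALTIQLIQNHFVDEYDPTIEDSYRKQVVIDGETCLLDILDTAG
QEEYSAMRDQYMRTGEGFLCVFAINNTKSFEDIHQYREQIKRVKDSDDVPMVLVGNKCDL
AARTVESRQAQDLARSYGIPYIETSAKTRQGVEDAFYTLVREIRQHKLRKLNPPDESGPG
CMSCKCVLS
>P62820_RAB1A_HUMAN transcribed copy of the canonical UniProt record; verify against UniProt when online
MSSMNPEYDYLFKLLLIGDSGVGKSCLLLRFADDTYTESYISTIGVDFKIRTIELDGKTI
KLQIWDTAGQERFRTITSSYYRGAHGIIVVYDVTDQESFNNVKQWLQEIDRYASENVNKL
LVGNKCDLTTKKVVDYTTAKEFADSLGIPFLETSAKNATNVEQSFMTMAAEIKKRMGPGA
TAGGAEKSNVKIQSTPVKQSGGGCC
>P62491_RAB11A_HUMAN_GDOMAIN residues 1-175 transcribed; positions that could not be verified are masked as X
MGTRDDEYDYLFKLLLIGDSGVGKSNLLSRFTRNEFNLESKSTIGVEFATRSIQVDGKTI
KAQIWDTAGQERYRAITSAYYRGAVGALLVYDIAKHLTYENVERWLKELRDHADSNIVIM
LVGNKSDLRHLRAVPTDEARAFAEKNGLSFIETSALDSTNVEEAFXXXXXEXYXI
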
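# Default organism catalog: a compact, user-extensible list of agents
# commonly recovered in neonatal units. Every organism is either a
# recognized pathogen or a common commensal; the distinction drives the
# split of laboratory-confirmed bloodstream infections.
staphylococcus_aureus:      {display: "Staphylococcus aureus",        class: recognized_pathogen}
escherichia_coli:           {display: "Escherichia coli",             class: recognized_pathogen}
klebsiella_pneumoniae:      {display: "Klebsiella pneumoniae",        class: recognized_pathogen}
enterobacter_cloacae:       {display: "Enterobacter cloacae",         class: recognized_pathogen}
serratia_marcescens:        {display: "Serratia marcescens",          class: recognized_pathogen}
pseudomonas_aeruginosa:     {display: "Pseudomonas aeruginosa",       class: recognized_pathogen}
enterococcus_faecalis:      {display: "Enterococcus faecalis",        class: recognized_pathogen}
enterococcus_faecium:       {display: "Enterococcus faecium",         class: recognized_pathogen}
streptococcus_agalactiae:   {display: "Streptococcus agalactiae",     class: recognized_pathogen}
candida_albicans:           {display: "Candida albicans",             class: recognized_pathogen}
staphylococcus_epidermidis: {display: "Staphylococcus epidermidis",   class: common_commensal}
staphylococcus_capitis:     {display: "Staphylococcus capitis",       class: common_commensal}
corynebacterium_species:    {display: "Corynebacterium species",      class: common_commensal}
micrococcus_species:        {display: "Micrococcus species",          class: common_commensal}
bacillus_species:           {display: "Bacillus species",             class: common_commensal}
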
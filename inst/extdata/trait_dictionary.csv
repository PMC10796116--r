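column,unit,description
temperature,degC,environment temperature of the solve
mu_per_day,1/day,optimal steady-state growth rate
carbon_fixation,fmol C/um^3/day,gross carbon fixation per biovolume
CUE,dimensionless,carbon use efficiency (1 - respiration/photosynthesis)
chlorophyll_density,g chl/um^3,chlorophyll-a mass per biovolume
q_cell,mol N/mol C,whole-cell nitrogen to carbon quota
volume,um^3,cell volume (sphere)
radius,um,cell radius (= 3 beta)
beta,um,volume-to-surface ratio
carbon_storage,mol C/um^3,carbon in glucose store plus respiratory and stress lipids
respiratory_mode,category,active dark respiratory pathway (glycolysis / lipid_degradation / none)
damaged_fraction,dimensionless,damaged share of the photosystem pool
p_ri,molecules/um^3,ribosome concentration
c_tag,molecules/um^3,stress-mitigation stored lipid concentration
status,category,solver status (optimal / nonviable / failed)
tie,logical,both respiratory pathways within growth tolerance
phi_ru,dimensionless,proteome investment in rubisco
phi_tr,dimensionless,proteome investment in nitrogen transporters
phi_ri,dimensionless,proteome investment in ribosomes
phi_p,dimensionless,proteome investment in photosystems
phi_re,dimensionless,proteome investment in repair proteins
phi_lb,dimensionless,proteome investment in lipid synthesis
phi_gl,dimensionless,proteome investment in glycolysis
phi_ld,dimensionless,proteome investment in lipid degradation
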
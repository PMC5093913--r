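ion,shannon_radius_pm,hydration_enthalpy_kJ_mol,chloride_ld50_low_mg_kg,chloride_ld50_high_mg_kg,citation
Ca,100,-1592.4,2301,2301,"radius Shannon (1976) Acta Cryst A32 751, octahedral; hydration enthalpy Smith (1977) J Chem Educ 54 540; LD50 CaCl2 rat oral, ChemIDplus/RTECS"
Ba,135,-1305,100,300,"radius Shannon (1976) Acta Cryst A32 751, octahedral; hydration enthalpy Smith (1977) J Chem Educ 54 540; LD50 BaCl2 rat oral range, ChemIDplus/RTECS"
Sr,118,-1445,1253,1253,"radius Shannon (1976) Acta Cryst A32 751, octahedral; hydration enthalpy Smith (1977) J Chem Educ 54 540; LD50 SrCl2 rat oral, ChemIDplus/RTECS"
Cd,95,-1807,107,107,"radius Shannon (1976) Acta Cryst A32 751, octahedral; hydration enthalpy Smith (1977) J Chem Educ 54 540; LD50 CdCl2 rat oral, ChemIDplus/RTECS"
Pb,98,-1479.9,1947,1947,"radius Shannon-type effective ionic radius, octahedral; hydration enthalpy Smith (1977) J Chem Educ 54 540; LD50 PbCl2 rat oral, ChemIDplus/RTECS"
Hg,102,-1824,47,47,"radius Shannon (1976) Acta Cryst A32 751, octahedral; hydration enthalpy Smith (1977) J Chem Educ 54 540; LD50 HgCl2 rat oral, ChemIDplus/RTECS"
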
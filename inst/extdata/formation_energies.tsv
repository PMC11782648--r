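name	formula	charge	phase	dGf0_kJ_mol	source
H2O	H2O	0	aqueous	-237.1	CRC Handbook, liquid water
H+	H	1	aqueous	0	reference species, standard state
OH-	OH	-1	aqueous	-157.2	CRC Handbook
NO3-	NO3	-1	aqueous	-111.3	CRC Handbook
NO2-	NO2	-1	aqueous	-32.2	CRC Handbook
NO	NO	0	gas	86.6	CRC Handbook
N2O	N2O	0	gas	104.2	CRC Handbook
N2	N2	0	gas	0	elemental reference, dinitrogen gas
NH4+	NH4	1	aqueous	-79.3	CRC Handbook
NH3	NH3	0	aqueous	-26.5	CRC Handbook
HS-	HS	-1	aqueous	12.1	CRC Handbook
H2S	H2S	0	aqueous	-27.8	CRC Handbook
S0	S	0	solid	0	elemental reference, rhombic sulfur
SO4-2	SO4	-2	aqueous	-744.5	CRC Handbook
SO3-2	SO3	-2	aqueous	-486.6	CRC Handbook
S2O3-2	S2O3	-2	aqueous	-522.5	Thauer et al. 1977
CO2	CO2	0	gas	-394.4	CRC Handbook
CO2(aq)	CO2	0	aqueous	-386.0	CRC Handbook
HCO3-	HCO3	-1	aqueous	-586.8	CRC Handbook
CO3-2	CO3	-2	aqueous	-527.8	CRC Handbook
CH3COO-	C2H3O2	-1	aqueous	-369.3	CRC Handbook, acetate
C2H5COO-	C3H5O2	-1	aqueous	-361.1	Thauer et al. 1977, propionate
C6H12O6	C6H12O6	0	aqueous	-917.2	Thauer et al. 1977, glucose
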
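study_id	label	induced_only	tissue
s1	Six-day-old seedlings, CATMA (this compendium)	FALSE	seedlings
s2	Six-week-old roots, CATMA (this compendium)	FALSE	roots
s3	Bauer and Blondet 2011	FALSE	mixed
s4	Ivanov et al. 2012	FALSE	roots
s5	Yang et al. 2010	FALSE	roots
s6a	Long et al. 2010, 48 h	FALSE	roots
s6b	Long et al. 2010, 72 h	FALSE	roots
s6c	Long et al. 2010, 24 h (WT vs pye)	FALSE	roots
s7	Garcia et al. 2010	TRUE	roots
s8	Buckhout et al. 2009	FALSE	roots
s9a	Dinneny et al. 2008, 48 h	FALSE	roots
s9b	Dinneny et al. 2008, 72 h	FALSE	roots
s10	Colangelo and Guerinot 2004	TRUE	roots
s11	Schuler et al. 2011	FALSE	mixed
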
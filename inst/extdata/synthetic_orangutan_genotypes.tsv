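sample_id	locus_id	genotype
O01	chr7_70375547	+/+
O02	chr7_70375547	+/+
O03	chr7_70375547	+/+
O04	chr7_70375547	+/+
O05	chr7_70375547	+/+
O06	chr7_70375547	+/+
O07	chr7_70375547	+/+
O08	chr7_70375547	+/+
O09	chr7_70375547	+/+
O10	chr7_70375547	+/+
O11	chr7_70375547	+/+
O12	chr7_70375547	+/+
O13	chr7_70375547	+/+
O14	chr7_70375547	+/+
O15	chr7_70375547	+/+
O16	chr7_70375547	+/+
O17	chr7_70375547	+/+
O18	chr7_70375547	+/+
O19	chr7_70375547	+/+
O20	chr7_70375547	+/+
O21	chr7_70375547	+/+
O22	chr7_70375547	+/+
O23	chr7_70375547	+/+
O24	chr7_70375547	+/+
O25	chr7_70375547	+/+
O26	chr7_70375547	+/+
O27	chr7_70375547	+/+
O28	chr7_70375547	+/+
O29	chr7_70375547	+/+
O30	chr7_70375547	+/+
O31	chr7_70375547	+/+
O32	chr7_70375547	+/+
O33	chr7_70375547	+/+
O34	chr7_70375547	+/+
O35	chr7_70375547	+/+
O36	chr7_70375547	+/+
O37	chr7_70375547	+/+
O01	chr12_90005006	+/+
O02	chr12_90005006	+/+
O03	chr12_90005006	+/+
O04	chr12_90005006	+/+
O05	chr12_90005006	+/+
O06	chr12_90005006	+/+
O07	chr12_90005006	+/+
O08	chr12_90005006	+/+
O09	chr12_90005006	+/+
O10	chr12_90005006	+/+
O11	chr12_90005006	+/+
O12	chr12_90005006	+/+
O13	chr12_90005006	+/-
O14	chr12_90005006	+/-
O15	chr12_90005006	+/-
O16	chr12_90005006	+/-
O17	chr12_90005006	+/-
O18	chr12_90005006	+/-
O19	chr12_90005006	+/-
O20	chr12_90005006	+/-
O21	chr12_90005006	+/-
O22	chr12_90005006	+/-
O23	chr12_90005006	+/-
O24	chr12_90005006	+/-
O25	chr12_90005006	+/-
O26	chr12_90005006	+/-
O27	chr12_90005006	+/-
O28	chr12_90005006	+/-
O29	chr12_90005006	-/-
O30	chr12_90005006	-/-
O31	chr12_90005006	-/-
O32	chr12_90005006	-/-
O33	chr12_90005006	-/-
O34	chr12_90005006	-/-
O35	chr12_90005006	-/-
O36	chr12_90005006	-/-
O37	chr12_90005006	-/-
O01	chr17_56932716	+/-
O02	chr17_56932716	+/-
O03	chr17_56932716	+/-
O04	chr17_56932716	+/-
O05	chr17_56932716	+/-
O06	chr17_56932716	+/-
O07	chr17_56932716	-/-
O08	chr17_56932716	-/-
O09	chr17_56932716	-/-
O10	chr17_56932716	-/-
O11	chr17_56932716	-/-
O12	chr17_56932716	-/-
O13	chr17_56932716	-/-
O14	chr17_56932716	-/-
O15	chr17_56932716	-/-
O16	chr17_56932716	-/-
O17	chr17_56932716	-/-
O18	chr17_56932716	-/-
O19	chr17_56932716	-/-
O20	chr17_56932716	-/-
O21	chr17_56932716	-/-
O22	chr17_56932716	-/-
O23	chr17_56932716	-/-
O24	chr17_56932716	-/-
O25	chr17_56932716	-/-
O26	chr17_56932716	-/-
O27	chr17_56932716	-/-
O28	chr17_56932716	-/-
O29	chr17_56932716	-/-
O30	chr17_56932716	-/-
O31	chr17_56932716	-/-
O32	chr17_56932716	-/-
O33	chr17_56932716	-/-
O34	chr17_56932716	-/-
O35	chr17_56932716	-/-
O36	chr17_56932716	-/-
O37	chr17_56932716	-/-
O01	chr13_109637257	+/+
O02	chr13_109637257	+/+
O03	chr13_109637257	+/-
O04	chr13_109637257	+/-
O05	chr13_109637257	+/-
O06	chr13_109637257	+/-
O07	chr13_109637257	+/-
O08	chr13_109637257	+/-
O09	chr13_109637257	+/-
O10	chr13_109637257	+/-
O11	chr13_109637257	+/-
O12	chr13_109637257	+/-
O13	chr13_109637257	+/-
O14	chr13_109637257	-/-
O15	chr13_109637257	-/-
O16	chr13_109637257	-/-
O17	chr13_109637257	-/-
O18	chr13_109637257	-/-
O19	chr13_109637257	-/-
O20	chr13_109637257	-/-
O21	chr13_109637257	-/-
O22	chr13_109637257	-/-
O23	chr13_109637257	-/-
O24	chr13_109637257	-/-
O25	chr13_109637257	-/-
O26	chr13_109637257	-/-
O27	chr13_109637257	-/-
O28	chr13_109637257	-/-
O29	chr13_109637257	-/-
O30	chr13_109637257	-/-
O31	chr13_109637257	-/-
O32	chr13_109637257	-/-
O33	chr13_109637257	-/-
O34	chr13_109637257	-/-
O35	chr13_109637257	-/-
O36	chr13_109637257	-/-
O37	chr13_109637257	-/-
O01	chr21_23655335	+/-
O02	chr21_23655335	+/-
O03	chr21_23655335	+/-
O04	chr21_23655335	+/-
O05	chr21_23655335	+/-
O06	chr21_23655335	+/-
O07	chr21_23655335	+/-
O08	chr21_23655335	-/-
O09	chr21_23655335	-/-
O10	chr21_23655335	-/-
O11	chr21_23655335	-/-
O12	chr21_23655335	-/-
O13	chr21_23655335	-/-
O14	chr21_23655335	-/-
O15	chr21_23655335	-/-
O16	chr21_23655335	-/-
O17	chr21_23655335	-/-
O18	chr21_23655335	-/-
O19	chr21_23655335	-/-
O20	chr21_23655335	-/-
O21	chr21_23655335	-/-
O22	chr21_23655335	-/-
O23	chr21_23655335	-/-
O24	chr21_23655335	-/-
O25	chr21_23655335	-/-
O26	chr21_23655335	-/-
O27	chr21_23655335	-/-
O28	chr21_23655335	-/-
O29	chr21_23655335	-/-
O30	chr21_23655335	-/-
O31	chr21_23655335	-/-
O32	chr21_23655335	-/-
O33	chr21_23655335	-/-
O34	chr21_23655335	-/-
O35	chr21_23655335	-/-
O36	chr21_23655335	-/-
O37	chr21_23655335	-/-
O01	chr2b_3809376	+/+
O02	chr2b_3809376	+/+
O03	chr2b_3809376	+/+
O04	chr2b_3809376	+/+
O05	chr2b_3809376	+/+
O06	chr2b_3809376	+/-
O07	chr2b_3809376	+/-
O08	chr2b_3809376	+/-
O09	chr2b_3809376	+/-
O10	chr2b_3809376	+/-
O11	chr2b_3809376	+/-
O12	chr2b_3809376	+/-
O13	chr2b_3809376	+/-
O14	chr2b_3809376	+/-
O15	chr2b_3809376	+/-
O16	chr2b_3809376	+/-
O17	chr2b_3809376	+/-
O18	chr2b_3809376	+/-
O19	chr2b_3809376	+/-
O20	chr2b_3809376	+/-
O21	chr2b_3809376	+/-
O22	chr2b_3809376	-/-
O23	chr2b_3809376	-/-
O24	chr2b_3809376	-/-
O25	chr2b_3809376	-/-
O26	chr2b_3809376	-/-
O27	chr2b_3809376	-/-
O28	chr2b_3809376	-/-
O29	chr2b_3809376	-/-
O30	chr2b_3809376	-/-
O31	chr2b_3809376	-/-
O32	chr2b_3809376	-/-
O33	chr2b_3809376	-/-
O34	chr2b_3809376	-/-
O35	chr2b_3809376	-/-
O36	chr2b_3809376	-/-
O37	chr2b_3809376	-/-
O01	chr17_18571864	+/+
O02	chr17_18571864	+/+
O03	chr17_18571864	+/+
O04	chr17_18571864	+/+
O05	chr17_18571864	+/+
O06	chr17_18571864	+/+
O07	chr17_18571864	+/+
O08	chr17_18571864	+/+
O09	chr17_18571864	+/+
O10	chr17_18571864	+/+
O11	chr17_18571864	+/+
O12	chr17_18571864	+/+
O13	chr17_18571864	+/+
O14	chr17_18571864	+/+
O15	chr17_18571864	+/+
O16	chr17_18571864	+/+
O17	chr17_18571864	+/+
O18	chr17_18571864	+/+
O19	chr17_18571864	+/+
O20	chr17_18571864	+/+
O21	chr17_18571864	+/+
O22	chr17_18571864	+/+
O23	chr17_18571864	+/+
O24	chr17_18571864	+/+
O25	chr17_18571864	+/+
O26	chr17_18571864	+/+
O27	chr17_18571864	+/+
O28	chr17_18571864	+/+
O29	chr17_18571864	+/+
O30	chr17_18571864	+/+
O31	chr17_18571864	+/+
O32	chr17_18571864	+/+
O33	chr17_18571864	+/+
O34	chr17_18571864	+/+
O35	chr17_18571864	+/+
O36	chr17_18571864	+/+
O37	chr17_18571864	+/+
O01	chr4_170477976	+/+
O02	chr4_170477976	+/+
O03	chr4_170477976	+/+
O04	chr4_170477976	+/+
O05	chr4_170477976	+/+
O06	chr4_170477976	+/+
O07	chr4_170477976	+/+
O08	chr4_170477976	+/+
O09	chr4_170477976	+/+
O10	chr4_170477976	+/+
O11	chr4_170477976	+/+
O12	chr4_170477976	+/+
O13	chr4_170477976	+/+
O14	chr4_170477976	+/+
O15	chr4_170477976	+/+
O16	chr4_170477976	+/+
O17	chr4_170477976	+/+
O18	chr4_170477976	+/+
O19	chr4_170477976	+/+
O20	chr4_170477976	+/+
O21	chr4_170477976	+/+
O22	chr4_170477976	+/+
O23	chr4_170477976	+/+
O24	chr4_170477976	+/+
O25	chr4_170477976	+/+
O26	chr4_170477976	+/+
O27	chr4_170477976	+/+
O28	chr4_170477976	+/+
O29	chr4_170477976	+/+
O30	chr4_170477976	+/+
O31	chr4_170477976	+/+
O32	chr4_170477976	+/+
O33	chr4_170477976	+/+
O34	chr4_170477976	+/+
O35	chr4_170477976	+/+
O36	chr4_170477976	+/+
O37	chr4_170477976	+/+
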
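rank	id_a	id_b	drug_a	drug_b	interaction
1	DB01194	DB00273	Brinzolamide	Topiramate	The risk or severity of adverse effects can be increased when Topiramate is combined with Brinzolamide
2	DB01589	DB00678	Quazepam	Losartan	The metabolism of Quazepam can be decreased when combined with Losartan
3	DB01212	DB00417	Ceftriaxone	PenicillinV	No interactions
4	DB01586	DB00951	Ursodeoxycholicacid	Isoniazid	No interactions
5	DB01337	DB00565	Pancuronium	Cisatracurium	Pancuronium may increase the central nervous system depressant (CNS depressant) activities of Cisatracurium
6	DB00351	DB00484	Megestrolacetate	Brimonidine	No interactions
7	DB00530	DB00445	Erlotinib	Epirubicin	No interactions
8	DB00458	DB00659	Imipramine	Acamprosate	No interactions
9	DB01586	DB00319	Ursodeoxycholicacid	Piperacillin	No interactions
10	DB00443	DB00333	Betamethasone	Methadone	The metabolism of Methadone can be increased when combined with Betamethasone
11	DB00458	DB00321	Imipramine	Amitriptyline	The metabolism of Amitriptyline can be decreased when combined with Imipramine
12	DB00790	DB00584	Perindopril	Enalapril	The risk or severity of angioedema can be increased when Enalapril is combined with Perindopril
13	DB01059	DB00448	Norfloxacin	Lansoprazole	No interactions
14	DB00571	DB01203	Propranolol	Nadolol	Propranolol may increase the arrhythmogenic activities of Nadolol
15	DB00975	DB00627	Dipyridamole	Niacin	No interactions
16	DB00967	DB01173	Desloratadine	Orphenadrine	Desloratadine may increase the central nervous system depressant (CNS depressant) activities of Orphenadrine
17	DB00222	DB00328	Glimepiride	Indomethacin	The protein binding of Glimepiride can be decreased when combined with Indomethacin
18	DB00193	DB01183	Tramadol	Naloxone	The metabolism of Naloxone can be decreased when combined with Tramadol
19	DB00904	DB00918	Ondansetron	Almotriptan	The risk or severity of adverse effects can be increased when Ondansetron is combined with Almotriptan
20	DB00423	DB00794	Methocarbamol	Primidone	The risk or severity of adverse effects can be increased when Methocarbamol is combined with Primidone
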
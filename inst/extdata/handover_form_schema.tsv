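# Default handover form schema: 6 headings + NA, 50 mutually exclusive categories
# (5, 18, 8, 12, 3, 3 categories under the six headings plus one NA category).
# Category names attested in the study prose are reproduced verbatim; the
# remaining slot names are a synthetic reconstruction (the published figure with
# the complete listing is graphical) and can be replaced by a user-supplied
# schema file with the same layout: id <TAB> heading <TAB> subheading <TAB> subsubheading
id	heading	subheading	subsubheading
1	HANDOVER NURSE	Title
2	HANDOVER NURSE	Given names/initials
3	HANDOVER NURSE	Last name
4	HANDOVER NURSE	Role
5	HANDOVER NURSE	Shift
6	PATIENT INTRODUCTION	Title
7	PATIENT INTRODUCTION	Given names/initials
8	PATIENT INTRODUCTION	Last name
9	PATIENT INTRODUCTION	Gender
10	PATIENT INTRODUCTION	Age
11	PATIENT INTRODUCTION	Date of birth	Year
12	PATIENT INTRODUCTION	Date of birth	Month
13	PATIENT INTRODUCTION	Date of birth	Day
14	PATIENT INTRODUCTION	Current room
15	PATIENT INTRODUCTION	Current bed
16	PATIENT INTRODUCTION	Responsible clinician
17	PATIENT INTRODUCTION	Admission reason/diagnosis
18	PATIENT INTRODUCTION	Admission date
19	PATIENT INTRODUCTION	In-patient time
20	PATIENT INTRODUCTION	Disease/problem history
21	PATIENT INTRODUCTION	Chronic condition
22	PATIENT INTRODUCTION	Allergy
23	PATIENT INTRODUCTION	Care plan
24	MY SHIFT	Status
25	MY SHIFT	Vital signs
26	MY SHIFT	Pain
27	MY SHIFT	Input/output
28	MY SHIFT	Wound/skin
29	MY SHIFT	Risk
30	MY SHIFT	Activities of daily living
31	MY SHIFT	Other observation
32	APPOINTMENTS	Description
33	APPOINTMENTS	Procedure
34	APPOINTMENTS	Clinician
35	APPOINTMENTS	Location
36	APPOINTMENTS	Date	Year
37	APPOINTMENTS	Date	Month
38	APPOINTMENTS	Date	Day
39	APPOINTMENTS	Time
40	APPOINTMENTS	Status
41	APPOINTMENTS	Preparation
42	APPOINTMENTS	Transport
43	APPOINTMENTS	Escort
44	MEDICATION	Medicine
45	MEDICATION	Dosage
46	MEDICATION	Status
47	FUTURE CARE	Goal/task to be completed/expected outcome
48	FUTURE CARE	Discharge/transfer plan
49	FUTURE CARE	Alert
50	NA	NA
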
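site,plot_id,date
laanila,laanila_1,2001-05-17
laanila,laanila_1,2002-05-01
laanila,laanila_1,2003-05-13
laanila,laanila_2,2008-05-26
laanila,laanila_2,2009-05-14
laanila,laanila_2,2010-05-18
vanttauskoski,vanttauskoski_1,2001-05-06
vanttauskoski,vanttauskoski_1,2002-04-30
vanttauskoski,vanttauskoski_1,2003-05-09
vanttauskoski,vanttauskoski_2,2008-05-21
vanttauskoski,vanttauskoski_2,2009-05-10
vanttauskoski,vanttauskoski_2,2010-05-13
vanttauskoski,vanttauskoski_3,2011-05-11
vanttauskoski,vanttauskoski_3,2012-05-12
vanttauskoski,vanttauskoski_3,2013-05-14
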
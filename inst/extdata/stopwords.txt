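a
an
the
and
or
but
nor
so
yet
for
of
in
on
at
by
to
from
with
without
about
above
below
under
over
between
among
through
during
before
after
into
onto
off
out
up
down
near
across
along
around
against
as
is
are
was
were
be
been
being
it
its
this
that
these
those
there
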